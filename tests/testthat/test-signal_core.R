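# signal_core: trimming, conversion, interpolation, artifact correction,
# segmentation, readers.

test_that("trailing zeros are trimmed, interior values untouched", {
  p <- trim_trailing_zeros(c(100, 900, 1700, 0, 0))
  expect_equal(p$times, c(100, 900, 1700))
  expect_equal(trim_trailing_zeros(c(100, 900, 1700))$times,
               c(100, 900, 1700))
  # a leading zero is a legitimate first sample index
  expect_equal(trim_trailing_zeros(c(0, 900, 1700, 0))$times, c(0, 900, 1700))
  expect_error(trim_trailing_zeros(c(0, 0, 0)), "insufficient beats")
})

test_that("peaks_to_rri implements the difference formula", {
  expect_equal(peaks_to_rri(c(0, 1000, 2000), 1000)$intervals, c(1000, 1000))
  expect_equal(peaks_to_rri(c(0, 500, 1100), 1000)$intervals, c(500, 600))
  expect_equal(peaks_to_rri(c(0, 250), 500)$intervals, 500)
  expect_error(peaks_to_rri(c(0, 500, 400), 1000), "non-monotone")
  expect_error(peaks_to_rri(c(42), 1000), "insufficient beats")
})

test_that("peaks_to_rri inverts cumulative summation (round trip)", {
  set.seed(11)
  for (rep in 1:5) {
    iv <- runif(50, 400, 1200)
    peaks <- cumsum(c(0, iv))           # sample indices at 1000 Hz
    expect_equal(peaks_to_rri(peaks, 1000)$intervals, iv)
  }
})

test_that("interpolate_rri preserves constants, ramps, and the rate floor", {
  iv <- rep(800, 20)
  pk <- peak_series(cumsum(c(0, iv)), 1000)
  out <- interpolate_rri(peaks_to_rri(pk), pk, target_rate = 4)
  expect_equal(out$rate, 10)            # 4 Hz promoted to the 10 Hz floor
  expect_true(all(abs(out$signal - 800) < 1e-9))

  iv2 <- seq(600, 1000, length.out = 21)[-1]
  pk2 <- peak_series(cumsum(c(0, iv2)), 1000)
  out2 <- interpolate_rri(peaks_to_rri(pk2), pk2, target_rate = 10)
  # linear interpolation is exact on a linear-in-time ramp of anchors
  anchors_t <- cumsum(iv2) / 1000
  inside <- out2$t >= anchors_t[1] & out2$t <= anchors_t[length(anchors_t)]
  ref <- approx(anchors_t, iv2, xout = out2$t[inside])$y
  expect_equal(out2$signal[inside], ref, tolerance = 1e-12)
  expect_error(interpolate_rri(rri_series(800), peak_series(c(0, 800))),
               "insufficient beats")
})

test_that("artifact corrector handles the three canonical cases", {
  base <- rep(800, 30)

  # clean input: unchanged, empty report
  pk <- peak_series(cumsum(c(0, base)), 1000)
  res <- correct_artifacts(pk, 0.4, 1.5)
  expect_equal(res$rri$intervals, base)
  expect_equal(nrow(res$report$corrections), 0L)

  # missed beat: a 1600 ms gap is split into two ~800 ms intervals
  gap <- c(rep(800, 10), 1600, rep(800, 10))
  res <- correct_artifacts(peak_series(cumsum(c(0, gap)), 1000), 0.4, 1.5)
  expect_equal(res$rri$intervals, rep(800, 22))
  expect_equal(res$report$corrections$class, "missed_inserted")
  expect_equal(res$report$corrections$before_ms, 1600)

  # extra beat: a 200 ms interval is merged with its neighbour
  extra <- c(rep(800, 10), 200, rep(800, 10))
  res <- correct_artifacts(peak_series(cumsum(c(0, extra)), 1000), 0.4, 1.5)
  expect_equal(res$report$corrections$class, "extra_merged")
  expect_true(all(res$rri$intervals >= 400 & res$rri$intervals <= 1500))

  # ectopic: short+long pair summing to ~2 local beats -> two interpolants
  ect <- c(rep(800, 10), 250, 1550, rep(800, 10))
  res <- correct_artifacts(peak_series(cumsum(c(0, ect)), 1000), 0.4, 1.5)
  expect_equal(res$rri$intervals, c(rep(800, 10), 900, 900, rep(800, 10)))
  expect_true(all(res$report$corrections$class == "ectopic_interpolated"))
})

test_that("artifact correction conserves duration, is idempotent, errors on
           uncorrectable input", {
  gap <- c(rep(800, 5), 1600, 200, rep(800, 5), 2450, rep(800, 5))
  pk <- peak_series(cumsum(c(0, gap)), 1000)
  res <- correct_artifacts(pk, 0.4, 1.5)
  expect_equal(sum(res$rri$intervals), sum(gap), tolerance = 1e-9)
  expect_true(all(res$rri$intervals >= 400 & res$rri$intervals <= 1500))
  # idempotent: re-running on corrected output yields zero corrections
  res2 <- correct_artifacts(res$peaks, 0.4, 1.5)
  expect_equal(nrow(res2$report$corrections), 0L)
  expect_equal(res2$rri$intervals, res$rri$intervals)
  # bounds excluding all data
  expect_error(correct_artifacts(peak_series(cumsum(c(0, rep(100, 10)))),
                                 0.4, 1.5),
               "uncorrectable")
})

test_that("correction count matches positions changed when lengths align", {
  x <- c(rep(800, 8), 250, 1550, rep(800, 8))  # ectopic pair: length kept
  res <- correct_artifacts(peak_series(cumsum(c(0, x)), 1000), 0.4, 1.5)
  expect_equal(length(res$rri$intervals), length(x))
  expect_equal(nrow(res$report$corrections),
               sum(res$rri$intervals != x))
})

test_that("segmentation follows the divider formula and conserves totals", {
  g <- make_stationary_rri(seed = 3, duration = 25 * 60)
  ss <- segment_series(g$peaks, g$rri, 5)
  expect_equal(length(ss$segments), 5L)      # 25 min / 5 min
  # conservation of beats and duration
  segs <- ss$segments
  expect_equal(sum(vapply(segs, function(s) length(s$rri$intervals),
                          integer(1))),
               length(g$rri$intervals))
  expect_equal(sum(vapply(segs, function(s) sum(s$rri$intervals),
                          numeric(1))),
               sum(g$rri$intervals), tolerance = 1e-9)
  expect_equal(unlist(lapply(segs, function(s) s$rri$intervals)),
               g$rri$intervals, ignore_attr = TRUE)

  # identity window and sub-window input
  g5 <- make_stationary_rri(seed = 4, duration = 5 * 60)
  s5 <- segment_series(g5$peaks, g5$rri, 5)
  expect_equal(length(s5$segments), 1L)
  expect_false(s5$last_partial)

  g2 <- make_stationary_rri(seed = 5, duration = 2 * 60)
  s2 <- segment_series(g2$peaks, g2$rri, 5)
  expect_equal(length(s2$segments), 1L)
  expect_true(s2$last_partial)
})

test_that("time-based windowing cuts at window multiples", {
  g <- make_stationary_rri(seed = 6, duration = 12 * 60)
  ss <- segment_series(g$peaks, g$rri, 5, mode = "time")
  durs <- vapply(ss$segments, function(s) sum(s$rri$intervals) / 1000,
                 numeric(1))
  expect_equal(length(durs), 3L)
  expect_true(all(abs(durs[1:2] - 300) < 2))  # within one beat of 5 min
  expect_true(ss$last_partial)
})

test_that("peak CSV reader round-trips, with and without header", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("peak", "0", "812", "1630"), tmp)
  expect_equal(read_peaks_csv(tmp)$times, c(0, 812, 1630))
  tmp2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0", "812", "1630"), tmp2)
  expect_equal(read_peaks_csv(tmp2)$times, c(0, 812, 1630))
})

test_that("MAT reader extracts a named variable row via python", {
  py <- Sys.which("python")
  expect_true(nzchar(py))  # pre-installed in this environment
  tmp <- tempfile(fileext = ".mat")
  on.exit(unlink(tmp))
  code <- sprintf(
    "import numpy, scipy.io; scipy.io.savemat(%s, {'fetal_Rpeaks': numpy.vstack([numpy.zeros(4)]*4 + [numpy.array([0.,410.,830.,1270.])])})",
    deparse(tmp))
  system2(py, c("-c", shQuote(code)))
  p <- read_peaks_mat(tmp, "fetal_Rpeaks", row = 5, sampling_rate = 1000)
  expect_equal(p$times, c(0, 410, 830, 1270))
})

test_that("artifact profiles reproduce the printed bpm limits", {
  prof <- artifact_profiles()
  maternal <- prof[prof$profile == "maternal", ]
  fetal <- prof[prof$profile == "fetal", ]
  expect_equal(maternal$bpm_max, 60 / 0.4)   # 150
  expect_equal(fetal$bpm_min, 60 / 0.75)     # 80
})
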
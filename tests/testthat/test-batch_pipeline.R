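# Registry width, segment-wise assembly, batch execution, sleep analysis.

# A reduced config keeps the full-pipeline tests fast without changing any
# scientific default that matters for the checked properties.
fast_config <- function(...) hrv_config(delay_max = 30, ...)

test_that("the registry is version-locked at 124 metric columns", {
  reg <- hrv_metric_registry()
  expect_length(reg, 124L)
  expect_false(any(duplicated(reg)))
})

test_that("a 25-minute recording yields 5 rows x 124 metric columns", {
  g <- make_stationary_rri(seed = 91, duration = 25 * 60)
  tab <- compute_hrv_segmentwise(g$peaks, g$rri, "S91", fast_config())
  expect_equal(nrow(tab), 5L)
  expect_equal(setdiff(names(tab), c("segment duration, s", "SubjectID")),
               hrv_metric_registry())
  expect_equal(tab[["segment duration, s"]],
               vapply(segment_series(g$peaks, g$rri, 5)$segments,
                      function(s) sum(s$rri$intervals) / 1000, numeric(1)))
  expect_true(all(tab$SubjectID == "S91"))
})

test_that("constant input propagates per metric contracts, never aborts", {
  iv <- rep(800, 400)
  pk <- peak_series(cumsum(c(0, iv)), 1000)
  tab <- compute_hrv_segmentwise(pk, rri_series(iv), "C",
                                 fast_config(window_minutes = NULL))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$RMSSD, 0)
  expect_equal(tab$SDNN, 0)
  expect_equal(tab$SampEn, 0)
  expect_true(is.na(tab$CSI))            # degenerate cloud
  expect_true(is.na(tab$RecurrenceRate)) # degenerate phase space, logged
  expect_equal(ncol(tab), 126L)
})

test_that("identical input yields identical tables and byte-identical CSVs", {
  g <- make_stationary_rri(seed = 92, duration = 11 * 60)
  t1 <- compute_hrv_segmentwise(g$peaks, g$rri, "S", fast_config())
  t2 <- compute_hrv_segmentwise(g$peaks, g$rri, "S", fast_config())
  expect_identical(t1, t2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_hrv_csv(t1, f1); write_hrv_csv(t2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # read-back agrees to 12 significant digits
  back <- read_hrv_csv(f1)
  for (cn in hrv_metric_registry()) {
    ok <- is.finite(t1[[cn]])
    if (!any(ok)) next   # all-NA columns read back typeless
    expect_equal(back[[cn]][ok], t1[[cn]][ok], tolerance = 1e-11, label = cn)
  }
})

test_that("run_batch produces per-stream outputs with pairing enforced", {
  dir <- withr::local_tempdir()
  files_f <- character(3); files_m <- character(3)
  for (i in 1:3) {
    gf <- generate_rri(synthetic_spec(mean_rri = 450, sd_rri = 15,
                                      duration = 6 * 60, seed = 100 + i))
    gm <- generate_rri(synthetic_spec(mean_rri = 850, sd_rri = 40,
                                      duration = 6 * 60, seed = 200 + i))
    files_f[i] <- file.path(dir, sprintf("f%02d.csv", i))
    files_m[i] <- file.path(dir, sprintf("m%02d.csv", i))
    write.csv(data.frame(peak = gf$peaks$times), files_f[i],
              row.names = FALSE)
    write.csv(data.frame(peak = gm$peaks$times), files_m[i],
              row.names = FALSE)
  }
  out <- withr::local_tempdir()
  res <- run_batch(
    streams = list(
      f = list(files = files_f, interval_min = 0.33, interval_max = 0.75),
      m = list(files = files_m, interval_min = 0.4, interval_max = 1.5)),
    config = fast_config(window_minutes = 3), output_dir = out)

  for (lab in c("f", "m")) {
    mt <- read_hrv_csv(file.path(out, paste0(lab, "metrics.csv")))
    expect_equal(length(unique(mt$SubjectID)), 3L)
    expect_equal(setdiff(names(mt), c("segment duration, s", "SubjectID")),
                 hrv_metric_registry())
    ht <- read_hrv_csv(file.path(out, paste0("higher_", lab,
                                             "metrics.csv")))
    expect_equal(length(unique(ht$SubjectID)), 3L)
    expect_true(file.exists(file.path(out, paste0(lab,
                                                  "_artifacts_log.csv"))))
  }
  expect_true(file.exists(res$run_log))
  expect_gt(length(readLines(res$run_log)), 3L)

  # unpaired streams are an explicit error naming the counts
  expect_error(
    run_batch(streams = list(f = list(files = files_f),
                             m = list(files = files_m[1:2])),
              config = fast_config(), output_dir = out),
    "unpaired streams")
  expect_error(run_batch(streams = list(), config = fast_config()),
               "no input files")
  expect_error(
    run_batch(streams = list(f = list(files = character(0))),
              config = fast_config(), output_dir = out),
    "no input files")
})

test_that("sleep label parsing: format, epochs, legality", {
  labs <- parse_sleep_labels(c("0 0", "3600 5"))
  expect_equal(labs$stage[2], 5L)        # REM = 5
  expect_equal(labs$t[2], 3600)

  labs30 <- parse_sleep_labels(sprintf("%d %d", seq(0, 300, 30),
                                       rep(c(0L, 2L), c(5, 6))))
  expect_equal(labs30$epoch_s, 30)

  expect_error(parse_sleep_labels("100 4"), "illegal stage code 4")
  expect_error(parse_sleep_labels(c("0 0", "abc 2")), "non-numeric")
  expect_error(parse_sleep_labels("12"), "malformed")
})

test_that("Spearman stage correlations: perfect monotone and reversal", {
  set.seed(93)
  n <- 12
  cv_rmssd <- sort(runif(n, 0.1, 0.6))
  summaries <- data.frame(SubjectID = paste0("S", 1:n),
                          `CV RMSSD` = cv_rmssd, check.names = FALSE)
  durations <- data.frame(N3 = seq(1000, 4000, length.out = n),
                          REM = rev(seq(500, 2000, length.out = n)))
  res <- correlate_metrics_with_stages(summaries, durations)
  r_n3 <- res$R[res$metric == "CV RMSSD" & res$stage == "N3"]
  r_rem <- res$R[res$metric == "CV RMSSD" & res$stage == "REM"]
  expect_equal(r_n3, 1)
  expect_equal(r_rem, -1)
  expect_true(all(res$significant[res$metric == "CV RMSSD"]))
  expect_error(correlate_metrics_with_stages(summaries[1:3, ],
                                             durations[1:3, ]),
               ">= 5 subjects")
})

test_that("Spearman stage holds its nominal type-I error", {
  set.seed(94)
  reps <- 300
  hits <- logical(reps)
  for (k in seq_len(reps)) {
    s <- data.frame(m = rnorm(30))
    d <- data.frame(N3 = rnorm(30))
    res <- correlate_metrics_with_stages(cbind(SubjectID = "x", s), d)
    hits[k] <- res$significant[1]
  }
  expect_gte(mean(hits), 0.02)   # nominal 0.05, ~3 SE band at 300 reps
  expect_lte(mean(hits), 0.09)
})

test_that("bpm conversion produces pseudo-RRI with a caution", {
  expect_warning(r <- bpm_to_rri(c(60, 75, 80)), "pseudo-RRI")
  expect_equal(r$intervals, c(1000, 800, 750))
  expect_error(suppressWarnings(bpm_to_rri(c(60, 0))), "finite and > 0")
})

test_that("CLI simulate and run round-trip via a YAML config", {
  dir <- withr::local_tempdir()
  expect_invisible(hrv_cli(c("simulate", "--out", dir, "--duration", "400",
                             "--seed", "3")))
  peaks_file <- file.path(dir, "synthetic_3_peaks.csv")
  expect_true(file.exists(peaks_file))
  cfg <- file.path(dir, "cfg.yaml")
  out <- file.path(dir, "out")
  writeLines(c(
    "sampling_rate: 1000",
    "window_minutes: 3",
    "delay_max: 30",
    paste0("output_dir: ", out),
    "streams:",
    "  s:",
    paste0("    files: [", peaks_file, "]")), cfg)
  hrv_cli(c("run", "--config", cfg))
  expect_true(file.exists(file.path(out, "smetrics.csv")))
  expect_true(file.exists(file.path(out, "higher_smetrics.csv")))
})
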
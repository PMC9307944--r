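# Synthetic RRI generator, sleep sessions, artifact injection.

test_that("generator is deterministic and honours degenerate specs", {
  sp <- synthetic_spec(duration = 120, seed = 42,
                       modulation = list(c(0.25, 20)))
  a <- generate_rri(sp); b <- generate_rri(sp)
  expect_identical(a$rri$intervals, b$rri$intervals)

  quiet <- generate_rri(synthetic_spec(sd_rri = 0, duration = 60, seed = 1))
  expect_true(all(abs(quiet$rri$intervals - 850) < 1))  # peak rounding only

  expect_error(synthetic_spec(mean_rri = 300, sd_rri = 100, seed = 1),
               "invalid spec")
})

test_that("generator mean/SD converge to the spec (law of large numbers)", {
  sp <- synthetic_spec(mean_rri = 850, sd_rri = 40, duration = 10000 * 0.86,
                       ar1_coeff = 0.3, seed = 7)
  g <- generate_rri(sp)
  expect_gte(length(g$rri$intervals), 10000)
  # expect_equal tolerance is relative: 2% of target
  expect_equal(mean(g$rri$intervals), 850, tolerance = 0.02)
  expect_equal(sd(g$rri$intervals), 40, tolerance = 0.02)
})

test_that("sleep session: label counting, round-trip durations, RMSSD
           ordering", {
  sess <- generate_sleep_session(list(c(0, 300), c(2, 600)), epoch_s = 30,
                                 seed = 5)
  expect_equal(sum(grepl(" 0$", sess$label_lines)), 10)   # 10 wake epochs
  expect_equal(sum(grepl(" 2$", sess$label_lines)), 20)   # 20 N2 epochs
  labs <- parse_sleep_labels(sess$label_lines)
  expect_equal(labs$epoch_s, 30)
  dur <- stage_durations(labs)
  expect_equal(unname(dur["0"]), 300)
  expect_equal(unname(dur["2"]), 600)

  single <- generate_sleep_session(list(c(3, 450)), epoch_s = 30, seed = 6)
  d1 <- stage_durations(parse_sleep_labels(single$label_lines))
  expect_equal(unname(d1["3"]), 450)

  # N3 has the lowest short-term variability by construction
  sched <- list(c(0, 300), c(2, 300), c(3, 300), c(5, 300))
  sess2 <- generate_sleep_session(sched, seed = 8)
  ss <- segment_series(sess2$peaks, sess2$rri, 5)
  rmssd <- vapply(ss$segments,
                  function(s) compute_time_domain(s$rri)$RMSSD, numeric(1))
  expect_equal(which.min(rmssd), 3L)     # the N3 segment

  expect_error(generate_sleep_session(list()), "empty")
  expect_error(generate_sleep_session(list(c(4, 100))), "illegal stage")
})

test_that("artifact injection: identity at zero rates, determinism,
           recoverability", {
  g <- make_stationary_rri(seed = 9, duration = 600)
  id <- inject_artifacts(g$rri, 0, 0, seed = 1)
  expect_identical(id$rri$intervals, g$rri$intervals)
  expect_equal(nrow(id$truth), 0L)

  a <- inject_artifacts(g$rri, 0.02, 0.02, seed = 2)
  b <- inject_artifacts(g$rri, 0.02, 0.02, seed = 2)
  expect_identical(a$rri$intervals, b$rri$intervals)
  expect_gt(nrow(a$truth), 0L)
  # injection conserves total duration
  expect_equal(sum(a$rri$intervals), sum(g$rri$intervals), tolerance = 1e-9)

  # corrector recovers the original within 2% RMS (bounds chosen so every
  # injected event is detectable: split parts < 0.55 s, merges > 1.5 s)
  peaks_cor <- peak_series(cumsum(c(0, a$rri$intervals)), 1000)
  fixed <- correct_artifacts(peaks_cor, 0.55, 1.5)
  expect_equal(length(fixed$rri$intervals), length(g$rri$intervals))
  rms <- sqrt(mean((fixed$rri$intervals - g$rri$intervals)^2))
  expect_lt(rms / mean(g$rri$intervals), 0.02)
})

test_that("label files round-trip through the parser exactly", {
  sess <- generate_sleep_session(list(c(0, 120), c(1, 150), c(5, 240)),
                                 epoch_s = 30, seed = 11)
  tmp <- withr::local_tempfile(fileext = ".txt")
  writeLines(sess$label_lines, tmp)
  labs <- parse_sleep_labels(tmp)
  dur <- stage_durations(labs)
  expect_equal(unname(dur["0"]), 120)
  expect_equal(unname(dur["1"]), 150)
  expect_equal(unname(dur["5"]), 240)
})
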
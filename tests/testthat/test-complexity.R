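# Entropy, fractal, DFA/MFDFA estimators against oracles and known limits.

test_that("SampEn and ApEn agree exactly with brute-force template counting", {
  set.seed(51)
  cases <- list(
    rnorm(120),
    850 + cumsum(rnorm(150, 0, 10)),
    sin(2 * pi * (1:100) / 25) + rnorm(100, 0, 0.2)
  )
  for (x in cases) {
    r_abs <- 0.2 * sd(x)
    expect_equal(entropy_sample(x, 2, r_abs, r_absolute = TRUE),
                 oracle_sampen(x, 2, r_abs))
    expect_equal(entropy_approximate(x, 2, r_abs, r_absolute = TRUE),
                 oracle_apen(x, 2, r_abs))
    # with a non-unit delay
    expect_equal(entropy_sample(x, 2, r_abs, delay = 3, r_absolute = TRUE),
                 oracle_sampen(x, 2, r_abs, delay = 3))
  }
})

test_that("entropies vanish on perfectly regular input", {
  cst <- rep(800, 100)
  expect_equal(entropy_sample(cst), 0)
  expect_equal(entropy_approximate(cst), 0)
  expect_equal(entropy_permutation(cst, 3), 0)
  expect_equal(entropy_shannon_binned(cst), 0)
  expect_equal(entropy_cumulative_residual(cst), 0)
  # strictly monotone, m = 3: a single ordinal pattern
  expect_equal(entropy_permutation(seq(1, 100), 3), 0)
})

test_that("SampEn orders white noise above a sine", {
  set.seed(52)
  noise <- rnorm(1000)
  sine <- sin(2 * pi * (1:1000) / 25)
  expect_gt(entropy_sample(noise, 2, 0.2), entropy_sample(sine, 2, 0.2))
})

test_that("entropy estimators are invariant to adding a constant", {
  g <- make_stationary_rri(seed = 53, duration = 300)
  x <- g$rri$intervals
  shift <- x + 500
  expect_equal(entropy_sample(x), entropy_sample(shift))
  expect_equal(entropy_approximate(x), entropy_approximate(shift))
  expect_equal(entropy_fuzzy(x), entropy_fuzzy(shift))
  expect_equal(entropy_permutation(x, 3), entropy_permutation(shift, 3))
  expect_equal(compute_dfa(x)$alpha, compute_dfa(shift)$alpha)
})

test_that("fuzzy entropy responds to tolerance and stays finite", {
  g <- make_stationary_rri(seed = 54, duration = 300)
  x <- g$rri$intervals
  f1 <- entropy_fuzzy(x, 2, 0.2)
  f2 <- entropy_fuzzy(x, 2, 0.4)
  expect_true(is.finite(f1) && is.finite(f2))
  expect_gt(f1, f2)   # wider tolerance -> more matches -> lower entropy
})

test_that("ordinal pattern distribution sums to 1; WPEn = PEn for equal
           weights", {
  g <- make_stationary_rri(seed = 55, duration = 200)
  pat <- hrvsuite:::ordinal_patterns(g$rri$intervals, 3, 1)
  p <- table(pat) / length(pat)
  expect_equal(sum(p), 1)
  # alternating +-a: every embedding vector has identical variance
  x <- rep(c(0, 10), 40)
  expect_equal(entropy_permutation(x, 3, weighted = TRUE),
               entropy_permutation(x, 3, weighted = FALSE))
})

test_that("multiscale entropy: scale-1 identity, noise decay, RCMSE
           robustness", {
  g <- make_stationary_rri(seed = 56, duration = 350)
  x <- g$rri$intervals
  ms <- entropy_multiscale(x, "MSE", scales = 1L)
  expect_equal(ms$value, entropy_sample(x, 2, 0.2))

  set.seed(57)
  wn <- rnorm(5000)
  curve <- entropy_multiscale(wn, "MSE", scales = c(1, 2, 4, 8))$curve
  expect_true(all(diff(curve) < 0))   # coarse-graining lowers white-noise HE

  # short series: single-offset counts can vanish where pooled counts survive
  set.seed(58)
  short <- rnorm(60)
  mse <- entropy_multiscale(short, "MSE", scales = c(1, 6, 10))
  rcm <- entropy_multiscale(short, "RCMSE", scales = c(1, 6, 10))
  expect_true(sum(is.na(rcm$curve)) <= sum(is.na(mse$curve)))
  expect_true(is.finite(rcm$value))
})

test_that("optimal delay: quarter period on a sine, 1 on white noise,
           bound respected", {
  x <- sin(2 * pi * (1:400) / 40)
  d <- estimate_optimal_delay(x, 30)
  expect_gte(d$delay, 8); expect_lte(d$delay, 12)
  # package AMI curve matches the loop-based oracle
  for (lag in c(1, 5, 10)) {
    expect_equal(d$ami[lag], oracle_ami(x, lag, 10), tolerance = 1e-12)
  }
  for (seed in 1:5) {
    set.seed(seed)
    expect_equal(estimate_optimal_delay(rnorm(300), 30)$delay, 1L)
  }
  expect_lte(estimate_optimal_delay(x, 5)$delay, 5L)
  # too-short series: missing delay
  expect_true(is.na(estimate_optimal_delay(rnorm(50), 100)$delay))
  # seconds conversion via the mean interval
  g <- make_stationary_rri(seed = 59, duration = 300)
  dd <- estimate_optimal_delay(g$rri$intervals, 30)
  expect_equal(dd$delay_s, dd$delay * mean(g$rri$intervals) / 1000)
})

test_that("LZ76 parse counts match hand-derived values", {
  expect_equal(hrvsuite:::lz76_count(rep(1L, 10)), 2L)
  # canonical example from the LZ76 literature: 0001101001000101 -> 6 words
  s <- as.integer(strsplit("0001101001000101", "")[[1]])
  expect_equal(hrvsuite:::lz76_count(s), 6L)
  expect_equal(hrvsuite:::lz76_count(c(0L, 1L)), 2L)
  # normalised LZC of long random binary series is near 1
  set.seed(60)
  lz <- complexity_lempelziv(rnorm(4096))
  expect_gt(lz$value, 0.8); expect_lt(lz$value, 1.3)
})

test_that("fractal dimensions hit their anchors", {
  # straight line (any slope, any offset): KFD exactly 1
  expect_equal(fractal_katz(seq(3, 500, length.out = 1000)), 1, tolerance = 1e-12)
  expect_equal(fractal_sevcik(rep(1, 100)), 1)
  expect_equal(fractal_nld(rep(5, 100)), 1)

  set.seed(61)
  # SDA of white noise ~ 1.5; PSD slope ~ 0; Hurst ~ 0.5
  wn <- rnorm(4096)
  expect_equal(fractal_sda(wn), 1.5, tolerance = 0.1)
  expect_equal(fractal_psdslope(wn), 0, tolerance = 0.15)
  set.seed(62)
  expect_lt(abs(hurst_rs(rnorm(10000)) - 0.5), 0.07)
  # Higuchi: white noise ~ 2, smooth curve near 1
  expect_gt(fractal_higuchi(wn), 1.8)
  expect_lt(fractal_higuchi(sin(2 * pi * (1:2000) / 500)), 1.3)
})

test_that("DFA recovers the known limits and respects data contracts", {
  set.seed(63)
  wn <- rnorm(10000)
  expect_equal(compute_dfa(wn, dfa_scales(16, 256))$alpha, 0.5,
               tolerance = 0.05)
  expect_equal(compute_dfa(cumsum(wn), dfa_scales(16, 256))$alpha, 1.5,
               tolerance = 0.1)
  # 50 beats cannot support the 16-64 range
  expect_true(is.na(compute_dfa(rnorm(50), dfa_scales(16, 64))$alpha))
})

test_that("MFDFA: monofractal narrow, cascade wide, q=2 reduces to DFA", {
  set.seed(64)
  wn <- rnorm(4096)
  sc <- dfa_scales(16, 512, 10)
  m_wn <- compute_mfdfa(wn, scales = sc)
  expect_lt(m_wn$Width, 0.3)
  casc <- binomial_cascade(12)
  m_c <- compute_mfdfa(casc, scales = sc)
  expect_gt(m_c$Width, m_wn$Width)

  d <- compute_dfa(wn, sc)$alpha
  m2 <- compute_mfdfa(wn, q_list = c(1.999, 2, 2.001), scales = sc)
  expect_equal(m2$h_q[2], d, tolerance = 0.05)
})

test_that("corrdim separates periodic from stochastic dynamics", {
  set.seed(65)
  sine <- sin(2 * pi * (1:800) / 40)
  noise <- rnorm(800)
  cd_sine <- fractal_corrdim(sine, m = 3)
  cd_noise <- fractal_corrdim(noise, m = 3)
  expect_lt(cd_sine, cd_noise)  # a closed curve fills less of phase space
})

test_that("cApEn stays finite on short regular series where templates are
           unique", {
  set.seed(66)
  x <- seq(1, 60) + rnorm(60, 0, 0.01)   # nearly all templates unique
  v <- entropy_approximate_corrected(x, 2, 0.2)
  expect_true(is.finite(v))
})
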
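# Fractal-dimension, scaling and symbolic-complexity estimators.
# All deterministic given input and parameters.

#' Katz fractal dimension
#'
#' Katz's waveform fractal dimension on the planar curve (sample index,
#' value): euclidean distances between successive points are summed (L) and
#' averaged (a); with d the maximum euclidean distance from the first
#' point, `KFD = log10(L/a) / (log10(L/a) + log10(d/L))`. A straight line
#' of any slope gives exactly 1.
#'
#' @param x Numeric series.
#' @param dx Abscissa spacing between successive samples (default 1).
#' @return KFD (>= 1 for non-degenerate curves).
#' @export
fractal_katz <- function(x, dx = 1) {
  n <- length(x)
  if (n < 3L) return(NA_real_)
  t <- (seq_len(n) - 1) * dx
  steps <- sqrt(diff(t)^2 + diff(x)^2)
  L <- sum(steps)
  if (L == 0) return(NA_real_)
  a <- mean(steps)
  d <- max(sqrt((t - t[1])^2 + (x - x[1])^2))
  m <- L / a
  log10(m) / (log10(m) + log10(d / L))
}

#' Higuchi fractal dimension
#'
#' Curve lengths `L(k)` over decimated sub-series for k = 1..k_max; HFD is
#' the slope of `log(L(k))` vs `log(1/k)`.
#'
#' @param x Numeric series.
#' @param k_max Maximum decimation factor (default 10).
#' @return HFD (in [1, 2] for 1-D curves).
#' @export
fractal_higuchi <- function(x, k_max = 10L) {
  n <- length(x)
  if (n < 2L * k_max) k_max <- max(2L, n %/% 4L)
  if (n < 8L) return(NA_real_)
  lk <- vapply(seq_len(k_max), function(k) {
    lm_k <- vapply(seq_len(k), function(m0) {
      idx <- seq(m0, n, by = k)
      if (length(idx) < 2L) return(NA_real_)
      norm <- (n - 1) / (length(idx) - 1) / k
      sum(abs(diff(x[idx]))) * norm / k
    }, numeric(1))
    mean(lm_k, na.rm = TRUE)
  }, numeric(1))
  if (any(lk <= 0)) return(NA_real_)
  stats::coef(stats::lm(log(lk) ~ log(1 / seq_len(k_max))))[[2]]
}

#' Petrosian fractal dimension
#'
#' Variant with the binary sequence built from sign changes of consecutive
#' differences: `PFD = log10(n) / (log10(n) + log10(n / (n + 0.4 Nd)))`
#' where `Nd` is the number of sign changes.
#'
#' @param x Numeric series.
#' @return PFD.
#' @export
fractal_petrosian <- function(x) {
  n <- length(x)
  if (n < 3L) return(NA_real_)
  d <- diff(x)
  s <- sign(d)
  s <- s[s != 0]
  nd <- if (length(s) > 1L) sum(diff(s) != 0) else 0L
  log10(n) / (log10(n) + log10(n / (n + 0.4 * nd)))
}

#' Sevcik fractal dimension
#'
#' Curve length after normalising both axes to the unit square:
#' `SFD = 1 + ln(L) / ln(2 (n - 1))`.
#'
#' @param x Numeric series.
#' @return SFD, 1 for a constant series.
#' @export
fractal_sevcik <- function(x) {
  n <- length(x)
  if (n < 3L) return(NA_real_)
  rng <- diff(range(x))
  if (rng == 0) return(1)
  ys <- (x - min(x)) / rng
  xs <- (seq_len(n) - 1) / (n - 1)
  L <- sum(sqrt(diff(ys)^2 + diff(xs)^2))
  1 + log(L) / log(2 * (n - 1))
}

#' Fractal dimension via normalized length density
#'
#' `NLD = mean(|diff(z)|)` of the z-scored signal, rescaled to an FD
#' estimate with the Kalauzi power model
#' `FD = 1.9079 (NLD - 0.097178)^0.18383`. Designed for very short epochs.
#'
#' @param x Numeric series.
#' @return FD estimate; 1 for a constant series, `NA` when the power-model
#'   base is negative.
#' @export
fractal_nld <- function(x) {
  if (length(x) < 3L) return(NA_real_)
  s <- stats::sd(x)
  if (s == 0) return(1)
  nld <- mean(abs(diff((x - mean(x)) / s)))
  base <- nld - 0.097178
  if (base <= 0) return(NA_real_)
  1.9079 * base^0.18383
}

#' Fractal dimension via standardized dispersion analysis
#'
#' The z-scored series is binned at dyadic bin sizes; the sample SD of the
#' bin means (dispersion, in SEM units) scales as a power of the bin size,
#' and `FD = 1 - slope` of the log-log fit. White noise gives slope -0.5,
#' hence FD 1.5; 1/f scaling approaches 1.2.
#'
#' @param x Numeric series.
#' @param scales Dyadic bin sizes; default `2, 4, ..., n/8`.
#' @return FD estimate.
#' @export
fractal_sda <- function(x, scales = NULL) {
  n <- length(x)
  if (n < 32L) return(NA_real_)
  s <- stats::sd(x)
  if (s == 0) return(NA_real_)
  z <- (x - mean(x)) / s
  if (is.null(scales)) {
    scales <- 2^(1:floor(log2(n / 8)))
  }
  scales <- scales[scales >= 2 & scales <= n / 4]
  disp <- vapply(scales, function(b) {
    nb <- n %/% b
    stats::sd(colMeans(matrix(z[seq_len(nb * b)], nrow = b)))
  }, numeric(1))
  keep <- disp > 0
  if (sum(keep) < 2L) return(NA_real_)
  slope <- stats::coef(stats::lm(log(disp[keep]) ~ log(scales[keep])))[[2]]
  1 - slope
}

#' Log-log power spectral density slope
#'
#' Least-squares slope of `log10(power)` versus `log10(frequency)` of the
#' mean-removed periodogram (zero frequency excluded). A slope near 0 is
#' white noise, around -1 pink noise, near -2 Brownian motion. The
#' corresponding FD of a 1-D curve is `(5 - slope_of_integrated)/2`; the
#' slope itself is reported.
#'
#' @param x Numeric series.
#' @return Spectral slope (dimensionless).
#' @export
fractal_psdslope <- function(x) {
  n <- length(x)
  if (n < 64L) return(NA_real_)
  x <- x - mean(x)
  if (all(x == 0)) return(NA_real_)
  p <- Mod(stats::fft(x))[2:(n %/% 2 + 1)]^2
  f <- seq_len(n %/% 2) / n
  keep <- p > 0
  if (sum(keep) < 8L) return(NA_real_)
  stats::coef(stats::lm(log10(p[keep]) ~ log10(f[keep])))[[2]]
}

#' Relative roughness
#'
#' Ratio of the lag-1 autocovariance to the lag-0 autocovariance (i.e. the
#' lag-1 autocorrelation), used to classify noise colour. The alternative
#' `2 * (1 - r1)` convention is available via `convention = "doubled"`.
#'
#' @param x Numeric series.
#' @param convention `"ratio"` (default, the literal definition) or
#'   `"doubled"`.
#' @return Relative roughness.
#' @export
relative_roughness <- function(x, convention = c("ratio", "doubled")) {
  convention <- match.arg(convention)
  if (length(x) < 3L || stats::var(x) == 0) return(NA_real_)
  r1 <- stats::acf(x, lag.max = 1L, plot = FALSE,
                   demean = TRUE)$acf[2, 1, 1]
  if (convention == "ratio") r1 else 2 * (1 - r1)
}

#' Hurst exponent by rescaled-range analysis
#'
#' Classic R/S analysis: for each window size the range of the cumulative
#' mean-removed sum is divided by the window SD; the Hurst exponent is the
#' slope of `log(R/S)` versus `log(size)`. White noise gives H near 0.5.
#'
#' @param x Numeric series.
#' @param sizes Window sizes; default log-spaced between 16 and n/4.
#' @return Hurst exponent estimate.
#' @export
hurst_rs <- function(x, sizes = NULL) {
  n <- length(x)
  if (n < 64L || stats::sd(x) == 0) return(NA_real_)
  if (is.null(sizes)) {
    sizes <- unique(round(exp(seq(log(16), log(n / 4), length.out = 10))))
  }
  rs <- vapply(sizes, function(w) {
    nw <- n %/% w
    vals <- vapply(seq_len(nw), function(k) {
      seg <- x[((k - 1) * w + 1):(k * w)]
      y <- cumsum(seg - mean(seg))
      s <- stats::sd(seg)
      if (s == 0) return(NA_real_)
      (max(y) - min(y)) / s
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  keep <- is.finite(rs) & rs > 0
  if (sum(keep) < 2L) return(NA_real_)
  stats::coef(stats::lm(log(rs[keep]) ~ log(sizes[keep])))[[2]]
}

#' Correlation dimension (Grassberger-Procaccia)
#'
#' Correlation sums of the delay-embedded series over log-spaced radii
#' between the 5th and 50th percentile of pairwise distances; CorrDim is
#' the log-log slope.
#'
#' @param x Numeric series.
#' @param m Embedding dimension (default 2).
#' @param delay Embedding delay (default 1).
#' @param n_radii Number of radii for the fit (default 10).
#' @return Correlation dimension estimate.
#' @export
fractal_corrdim <- function(x, m = 2L, delay = 1L, n_radii = 10L) {
  if (length(x) < 20L * m) return(NA_real_)
  emb <- delay_embed(x, m, delay)
  d <- cheb_dist(emb)
  dv <- d[upper.tri(d)]
  dv <- dv[dv > 0]
  if (length(dv) < 50L) return(NA_real_)
  q <- stats::quantile(dv, c(0.05, 0.5), names = FALSE)
  if (q[1] <= 0 || q[2] <= q[1]) return(NA_real_)
  radii <- exp(seq(log(q[1]), log(q[2]), length.out = n_radii))
  cs <- vapply(radii, function(r) mean(dv <= r), numeric(1))
  keep <- cs > 0
  if (sum(keep) < 3L) return(NA_real_)
  stats::coef(stats::lm(log(cs[keep]) ~ log(radii[keep])))[[2]]
}

# LZ76 exhaustive-production parse count of a symbol vector
# (Kaspar & Schuster's formulation; 1-based indices).
lz76_count <- function(s) {
  n <- length(s)
  if (n == 0L) return(0L)
  if (n == 1L) return(1L)
  i <- 0L; k <- 1L; l <- 1L; k_max <- 1L; cn <- 1L
  repeat {
    if (s[i + k] == s[l + k]) {
      k <- k + 1L
      if (l + k > n) { cn <- cn + 1L; break }
    } else {
      if (k > k_max) k_max <- k
      i <- i + 1L
      if (i == l) {
        cn <- cn + 1L
        l <- l + k_max
        if (l + 1L > n) break
        i <- 0L; k <- 1L; k_max <- 1L
      } else {
        k <- 1L
      }
    }
  }
  cn
}

#' Lempel-Ziv complexity
#'
#' LZ76 production-parse count of the symbolised series, normalised by
#' `n / log_alpha(n)` (its expected growth for random sequences), where
#' alpha is the alphabet size. Default symbolisation is a binary split at
#' the median; `permutation = TRUE` uses ordinal patterns of order
#' `order` instead (PLZC).
#'
#' @param x Numeric series.
#' @param permutation Symbolise by ordinal patterns instead of the median
#'   split.
#' @param order Ordinal pattern order for PLZC (default 3).
#' @param delay Embedding delay for the ordinal patterns.
#' @return List with `count` (raw LZ76 parse count) and `value`
#'   (normalised complexity).
#' @export
complexity_lempelziv <- function(x, permutation = FALSE, order = 3L,
                                 delay = 1L) {
  if (permutation) {
    if (length(x) <= (order - 1L) * delay) {
      return(list(count = NA_integer_, value = NA_real_))
    }
    pat <- ordinal_patterns(x, order, delay)
    sym <- as.integer(factor(pat, levels = unique(pat)))
    alpha <- factorial(order)
  } else {
    sym <- as.integer(x > stats::median(x))
    alpha <- 2L
  }
  n <- length(sym)
  if (n < 2L) return(list(count = NA_integer_, value = NA_real_))
  cnt <- lz76_count(sym)
  list(count = cnt, value = cnt * log(n, base = alpha) / n)
}

#' Hjorth complexity
#'
#' Ratio of the mobility of the first difference to the mobility of the
#' signal, with mobility `sd(diff(x))/sd(x)`.
#'
#' @param x Numeric series.
#' @return Hjorth complexity (dimensionless).
#' @export
hjorth_complexity <- function(x) {
  if (length(x) < 4L) return(NA_real_)
  mob <- function(v) {
    s <- stats::sd(v)
    if (s == 0) return(NA_real_)
    stats::sd(diff(v)) / s
  }
  m1 <- mob(x); m2 <- mob(diff(x))
  if (is.na(m1) || is.na(m2)) return(NA_real_)
  m2 / m1
}
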
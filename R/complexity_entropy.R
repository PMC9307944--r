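# Entropy-family estimators. All operate on a plain numeric vector (an RRI
# segment) and are deterministic given input and parameters.

# Delay embedding: rows are vectors (x_i, x_{i+tau}, ..., x_{i+(m-1)tau}).
delay_embed <- function(x, m, tau = 1L) {
  n <- length(x) - (m - 1L) * tau
  if (n < 1L) stop("series too short for embedding")
  idx <- outer(seq_len(n), (seq_len(m) - 1L) * tau, "+")
  matrix(x[idx], nrow = n, ncol = m)
}

# Chebyshev distance matrix between rows of an embedding.
cheb_dist <- function(emb) {
  n <- nrow(emb)
  d <- matrix(0, n, n)
  for (k in seq_len(ncol(emb))) {
    d <- pmax(d, abs(outer(emb[, k], emb[, k], "-")))
  }
  d
}

# Tolerance resolution: r is a fraction of the series SD unless absolute.
resolve_tolerance <- function(x, r = 0.2, absolute = FALSE) {
  if (absolute) r else r * stats::sd(x)
}

#' Approximate entropy
#'
#' Pincus' ApEn with Chebyshev distance; self-matches are included, so the
#' estimate is always finite. `phi(m) - phi(m+1)` with
#' `phi(m) = mean_i log(C_i^m / N_m)`.
#'
#' @param x Numeric series.
#' @param m Embedding dimension (default 2).
#' @param r Tolerance as a fraction of `sd(x)` (default 0.2), or absolute
#'   when `r_absolute = TRUE`.
#' @param delay Embedding delay in samples/beats (default 1).
#' @param r_absolute Interpret `r` as an absolute distance.
#' @return ApEn (non-negative up to floating error) or `NA` if too short.
#' @export
entropy_approximate <- function(x, m = 2L, r = 0.2, delay = 1L,
                                r_absolute = FALSE) {
  if (length(x) <= (m + 1L) * delay + 1L) return(NA_real_)
  tol <- resolve_tolerance(x, r, r_absolute)
  phi <- function(mm) {
    emb <- delay_embed(x, mm, delay)
    cnt <- rowSums(cheb_dist(emb) <= tol)
    mean(log(cnt / nrow(emb)))
  }
  phi(m) - phi(m + 1L)
}

#' Corrected approximate entropy (cApEn)
#'
#' Porta-style correction: template pairs are counted with self-matches as
#' in ApEn, but conditional terms where either count equals one (the
#' template matches only itself) are replaced by `log(1/N)`, removing the
#' self-match bias that drives ApEn toward zero on short series.
#'
#' @inheritParams entropy_approximate
#' @return cApEn or `NA` if the series is too short.
#' @export
entropy_approximate_corrected <- function(x, m = 2L, r = 0.2, delay = 1L,
                                          r_absolute = FALSE) {
  n_upper <- length(x) - (m + 1L) * delay
  if (n_upper < 2L) return(NA_real_)
  tol <- resolve_tolerance(x, r, r_absolute)
  cnt_m <- rowSums(cheb_dist(delay_embed(x, m, delay)) <= tol)
  cnt_m1 <- rowSums(cheb_dist(delay_embed(x, m + 1L, delay)) <= tol)
  s <- vapply(seq_len(n_upper), function(i) {
    if (cnt_m[i] != 1 && cnt_m1[i] != 1) log(cnt_m1[i] / cnt_m[i])
    else log(1 / n_upper)
  }, numeric(1))
  -mean(s)
}

#' Sample entropy
#'
#' Richman & Moorman's SampEn: `-log(A/B)` where `B` and `A` count template
#' pairs (i < j, self-matches excluded) within tolerance at lengths `m` and
#' `m + 1`; both counts use the same `N - m*delay` templates.
#'
#' @inheritParams entropy_approximate
#' @return SampEn, or `NA` when no m-length template pair matches (logged
#'   upstream; never infinite).
#' @export
entropy_sample <- function(x, m = 2L, r = 0.2, delay = 1L,
                           r_absolute = FALSE) {
  nt <- length(x) - m * delay
  if (nt < 2L) return(NA_real_)
  tol <- resolve_tolerance(x, r, r_absolute)
  emb_m <- delay_embed(x, m, delay)[seq_len(nt), , drop = FALSE]
  emb_m1 <- delay_embed(x, m + 1L, delay)
  dm <- cheb_dist(emb_m)
  dm1 <- cheb_dist(emb_m1)
  ut <- upper.tri(dm)
  B <- sum(dm[ut] <= tol)
  A <- sum(dm1[upper.tri(dm1)] <= tol)
  if (B == 0 || A == 0) return(NA_real_)
  -log(A / B)
}

#' Fuzzy entropy
#'
#' Chen et al.'s FuzzEn: templates are centred by their own mean and
#' similarity is graded by the exponential membership
#' `exp(-(d/r)^n_exp)` (default `n_exp = 2`) of the Chebyshev distance.
#' `FuzzEn = log(phi_m / phi_{m+1})` over pair-mean memberships.
#'
#' @inheritParams entropy_approximate
#' @param n_exp Fuzzy membership exponent (default 2).
#' @return FuzzEn or `NA` if too short.
#' @export
entropy_fuzzy <- function(x, m = 2L, r = 0.2, delay = 1L, n_exp = 2,
                          r_absolute = FALSE) {
  nt <- length(x) - m * delay
  if (nt < 2L) return(NA_real_)
  tol <- resolve_tolerance(x, r, r_absolute)
  if (tol <= 0) return(0)
  phi <- function(mm) {
    emb <- delay_embed(x, mm, delay)[seq_len(nt), , drop = FALSE]
    emb <- emb - rowMeans(emb)
    d <- cheb_dist(emb)
    mu <- exp(-(d / tol)^n_exp)
    ut <- upper.tri(mu)
    mean(mu[ut])
  }
  p1 <- phi(m); p2 <- phi(m + 1L)
  if (p1 <= 0 || p2 <= 0) return(NA_real_)
  log(p1 / p2)
}

# Histogram symbolization used for Shannon-type entropies on continuous
# series: ceiling(sqrt(n)) equal-width bins over the data range.
symbolize_bins <- function(x, bins = NULL) {
  if (is.null(bins)) bins <- max(1L, ceiling(sqrt(length(x))))
  rng <- range(x)
  if (diff(rng) == 0) return(rep(1L, length(x)))
  br <- seq(rng[1], rng[2], length.out = bins + 1L)
  findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
}

# Shannon entropy of a symbol vector, base 2.
shannon <- function(sym, base = 2) {
  p <- table(sym) / length(sym)
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Shannon entropy of a binned series
#'
#' Continuous values are symbolised into `ceiling(sqrt(n))` equal-width
#' histogram bins before Shannon entropy (log base 2). A constant series
#' has entropy 0.
#'
#' @param x Numeric series.
#' @param bins Number of bins; `NULL` for the square-root default.
#' @return Entropy in bits.
#' @export
entropy_shannon_binned <- function(x, bins = NULL) {
  shannon(symbolize_bins(x, bins))
}

#' Spectral entropy
#'
#' Shannon entropy of the normalised power spectrum (periodogram of the
#' mean-removed series), normalised by the log of the number of frequency
#' bins so the value lies in [0, 1]. `NA` for a constant series.
#'
#' @param x Numeric series.
#' @return Normalised spectral entropy in [0, 1].
#' @export
entropy_spectral <- function(x) {
  x <- x - mean(x)
  if (all(x == 0)) return(NA_real_)
  n <- length(x)
  px <- Mod(stats::fft(x))[2:(n %/% 2 + 1)]^2
  tot <- sum(px)
  if (tot <= 0) return(NA_real_)
  p <- px / tot
  p <- p[p > 0]
  -sum(p * log(p)) / log(length(px))
}

#' Singular value decomposition entropy
#'
#' Shannon entropy (base 2) of the normalised singular values of the
#' delay-embedding matrix: how many orthogonal components the embedded
#' dynamics need.
#'
#' @param x Numeric series.
#' @param m Embedding dimension (default 2).
#' @param delay Embedding delay (default 1).
#' @return SVD entropy in bits.
#' @export
entropy_svd <- function(x, m = 2L, delay = 1L) {
  if (length(x) <= (m - 1L) * delay + 1L) return(NA_real_)
  sv <- svd(delay_embed(x, m, delay))$d
  if (sum(sv) == 0) return(0)
  p <- sv / sum(sv)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Ordinal pattern codes for permutation entropy. Ties are broken by
# position (stable order), so a constant window is one fixed pattern.
ordinal_patterns <- function(x, m = 3L, delay = 1L) {
  emb <- delay_embed(x, m, delay)
  apply(emb, 1L, function(v) {
    paste(order(v), collapse = "")
  })
}

#' Permutation entropy (and weighted variant)
#'
#' Shannon entropy of the ordinal-pattern distribution of the
#' delay-embedded series, normalised by `log2(m!)` to [0, 1]. The weighted
#' variant weights each pattern occurrence by the variance of its
#' embedding vector, retaining amplitude information.
#'
#' @param x Numeric series.
#' @param m Ordinal pattern order / embedding dimension (default 3).
#' @param delay Embedding delay (default 1).
#' @param weighted Compute weighted permutation entropy.
#' @return Normalised (weighted) permutation entropy in [0, 1].
#' @export
entropy_permutation <- function(x, m = 3L, delay = 1L, weighted = FALSE) {
  if (length(x) <= (m - 1L) * delay) return(NA_real_)
  pat <- ordinal_patterns(x, m, delay)
  if (weighted) {
    emb <- delay_embed(x, m, delay)
    w <- apply(emb, 1L, function(v) mean((v - mean(v))^2))
    if (sum(w) == 0) return(0)           # constant series: single pattern
    p <- tapply(w, pat, sum) / sum(w)
  } else {
    p <- table(pat) / length(pat)
  }
  p <- p[p > 0]
  h <- -sum(p * log2(p))
  h / log2(factorial(m))
}

#' Multiscale permutation entropy
#'
#' Mean of the permutation entropy of coarse-grained series (non-overlapping
#' window means) over the requested scales.
#'
#' @inheritParams entropy_permutation
#' @param scales Integer coarse-graining factors (default 1:5).
#' @return Mean normalised permutation entropy across valid scales.
#' @export
entropy_permutation_ms <- function(x, m = 3L, delay = 1L, scales = 1:5) {
  vals <- vapply(scales, function(s) {
    cg <- coarse_grain(x, s)
    if (length(cg) <= (m - 1L) * delay) return(NA_real_)
    entropy_permutation(cg, m, delay)
  }, numeric(1))
  if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
}

#' Cumulative residual entropy
#'
#' `-integral of S(x) log S(x) dx` over the empirical survival function S.
#' Non-negative by construction; 0 for a constant series.
#'
#' @param x Numeric series.
#' @return CREn (units of `x`).
#' @export
entropy_cumulative_residual <- function(x) {
  xs <- sort(unique(x))
  if (length(xs) < 2L) return(0)
  n <- length(x)
  # survival just above each distinct value
  surv <- vapply(xs, function(v) sum(x > v) / n, numeric(1))
  dx <- diff(xs)
  s <- surv[-length(surv)]
  keep <- s > 0
  -sum(s[keep] * log(s[keep]) * dx[keep])
}

#' Differential entropy via histogram density
#'
#' `-sum p_i log(p_i / width_i)` on an equal-width histogram with
#' `ceiling(sqrt(n))` bins. May be negative (a property of differential
#' entropy, not an error).
#'
#' @param x Numeric series.
#' @param bins Number of bins; `NULL` for the square-root default.
#' @return Differential entropy in nats, `NA` for constant input.
#' @export
entropy_differential <- function(x, bins = NULL) {
  if (is.null(bins)) bins <- max(1L, ceiling(sqrt(length(x))))
  rng <- range(x)
  if (diff(rng) == 0) return(NA_real_)
  h <- diff(rng) / bins
  p <- tabulate(symbolize_bins(x, bins), nbins = bins) / length(x)
  p <- p[p > 0]
  -sum(p * log(p / h))
}

#' Fisher information (singular-spectrum form)
#'
#' `sum_i (sigma_{i+1} - sigma_i)^2 / sigma_i` over the normalised singular
#' values of the delay-embedding matrix; a measure of spectral order
#' complementary to SVD entropy.
#'
#' @inheritParams entropy_svd
#' @return Fisher information (dimensionless).
#' @export
fisher_information <- function(x, m = 2L, delay = 1L) {
  if (length(x) <= (m - 1L) * delay + 1L) return(NA_real_)
  sv <- svd(delay_embed(x, m, delay))$d
  if (sum(sv) == 0) return(NA_real_)
  p <- sv / sum(sv)
  if (length(p) < 2L) return(0)
  i <- seq_len(length(p) - 1L)
  keep <- p[i] > 0
  sum(((p[i + 1L] - p[i])^2 / p[i])[keep])
}

# Coarse-grain a series by non-overlapping means at the given scale,
# starting from `offset` (1-based; offsets > 1 give the composite variants).
coarse_grain <- function(x, scale, offset = 1L) {
  x <- x[offset:length(x)]
  nwin <- length(x) %/% scale
  if (nwin < 1L) return(numeric(0))
  colMeans(matrix(x[seq_len(nwin * scale)], nrow = scale))
}

# Raw A/B template-match counts for SampEn-style entropy at one scale;
# fuzzy = TRUE uses summed memberships instead of counts.
.match_counts <- function(x, m, tol, delay = 1L, fuzzy = FALSE, n_exp = 2) {
  nt <- length(x) - m * delay
  if (nt < 2L) return(c(A = 0, B = 0))
  emb_m <- delay_embed(x, m, delay)[seq_len(nt), , drop = FALSE]
  emb_m1 <- delay_embed(x, m + 1L, delay)
  if (fuzzy) {
    emb_m <- emb_m - rowMeans(emb_m)
    emb_m1 <- emb_m1 - rowMeans(emb_m1)
    dB <- cheb_dist(emb_m); dA <- cheb_dist(emb_m1)
    B <- sum(exp(-(dB[upper.tri(dB)] / tol)^n_exp))
    A <- sum(exp(-(dA[upper.tri(dA)] / tol)^n_exp))
  } else {
    dB <- cheb_dist(emb_m); dA <- cheb_dist(emb_m1)
    B <- sum(dB[upper.tri(dB)] <= tol)
    A <- sum(dA[upper.tri(dA)] <= tol)
  }
  c(A = A, B = B)
}

#' Multiscale entropy family
#'
#' Multiscale (MSE), composite (CMSE), refined composite (RCMSE) sample
#' entropy and their fuzzy counterparts. Coarse-graining is by
#' non-overlapping means; CMSE averages the entropy over all offsets of a
#' scale, RCMSE pools the match counts across offsets before the log (so it
#' survives scales where a single offset has zero matches). The tolerance
#' is fixed from the SD of the original series (standard for MSE). The
#' summary value is the mean over valid scales.
#'
#' @param x Numeric series.
#' @param variant One of "MSE", "CMSE", "RCMSE", "FuzzEnMSE", "FuzzEnRCMSE".
#' @param m Embedding dimension (default 2).
#' @param r Tolerance fraction of `sd(x)` (default 0.2).
#' @param scales Integer scales (default 1:10, trimmed to the data).
#' @param delay Embedding delay (default 1).
#' @return List with `value` (mean over valid scales) and `curve`
#'   (per-scale values, NA where undefined).
#' @export
entropy_multiscale <- function(x,
                               variant = c("MSE", "CMSE", "RCMSE",
                                           "FuzzEnMSE", "FuzzEnRCMSE"),
                               m = 2L, r = 0.2, scales = 1:10, delay = 1L) {
  variant <- match.arg(variant)
  fuzzy <- grepl("FuzzEn", variant)
  refined <- grepl("RCMSE", variant)
  composite <- refined || variant == "CMSE"
  tol <- resolve_tolerance(x, r)
  if (tol <= 0) {     # constant series: zero entropy at every scale
    return(list(value = 0, curve = rep(0, length(scales)), scales = scales))
  }
  curve <- vapply(scales, function(s) {
    offsets <- if (composite) seq_len(s) else 1L
    ab <- vapply(offsets, function(o) {
      cg <- coarse_grain(x, s, o)
      if (length(cg) < (m + 1L) * delay + 2L) return(c(A = NA, B = NA))
      .match_counts(cg, m, tol, delay, fuzzy = fuzzy)
    }, numeric(2))
    if (all(is.na(ab))) return(NA_real_)
    if (refined) {
      A <- sum(ab["A", ], na.rm = TRUE); B <- sum(ab["B", ], na.rm = TRUE)
      if (A <= 0 || B <= 0) return(NA_real_)
      -log(A / B)
    } else {
      vals <- -log(ab["A", ] / ab["B", ])
      vals[!is.finite(vals)] <- NA
      if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
    }
  }, numeric(1))
  value <- if (all(is.na(curve))) NA_real_ else mean(curve, na.rm = TRUE)
  list(value = value, curve = curve, scales = scales)
}

# Average mutual information at one lag via 2-D equal-width histogram.
ami_lag <- function(x, lag, bins) {
  n <- length(x) - lag
  a <- symbolize_bins(x, bins)[seq_len(n)]
  b <- symbolize_bins(x, bins)[(lag + 1L):length(x)]
  pj <- table(a, b) / n
  pa <- rowSums(pj); pb <- colSums(pj)
  idx <- which(pj > 0, arr.ind = TRUE)
  sum(pj[idx] * log(pj[idx] / (pa[idx[, 1]] * pb[idx[, 2]])))
}

#' Optimal embedding delay (Fraser-Swinney)
#'
#' First local minimum of the average mutual information over lags
#' `1..delay_max`, falling back to the global minimum when AMI decreases
#' monotonically. AMI uses an equal-width decile histogram (10 bins,
#' fewer for very short series); a flatness guard returns delay 1 when no
#' lag dips below the lag-1 AMI by more than the histogram-MI
#' independence bias, as for i.i.d. data.
#'
#' @param x Numeric series (typically an RRI segment).
#' @param delay_max Largest lag to consider (default 100).
#' @return List with `delay` (beats), `delay_s` (seconds, via the mean
#'   interval when the input is in ms) and `ami` (the AMI curve);
#'   `delay = NA` when the series is shorter than `2 * delay_max`
#'   (dependent metrics then revert to delay 1).
#' @export
estimate_optimal_delay <- function(x, delay_max = 100L) {
  x <- as_numeric_series(x)
  delay_max <- as.integer(delay_max)
  if (length(x) <= 2L * delay_max || delay_max < 1L) {
    return(list(delay = NA_integer_, delay_s = NA_real_, ami = numeric(0)))
  }
  # decile histogram by default, fewer bins for very short series
  bins <- max(4L, min(10L, length(x) %/% 10L))
  ami <- vapply(seq_len(delay_max), function(l) ami_lag(x, l, bins),
                numeric(1))
  # Flatness guard: for i.i.d. data the AMI curve is flat up to the
  # histogram-MI independence bias ~ (B-1)^2 / (2n) nats; when no lag dips
  # below lag 1 by more than twice that bias there is no structure to
  # exploit and the first lag is optimal.
  bias <- (bins - 1)^2 / length(x)
  d <- NA_integer_
  if (ami[1L] - min(ami) <= bias) {
    d <- 1L
  } else if (delay_max >= 3L) {
    # first local minimum of the 3-point smoothed curve (Fraser-Swinney),
    # smoothing suppresses binning-parity ripple
    sm <- stats::filter(ami, rep(1 / 3, 3), sides = 2)
    for (i in 2:(delay_max - 1L)) {
      if (!is.na(sm[i]) && !is.na(sm[i + 1L]) &&
          sm[i] < sm[i - 1L] && sm[i] <= sm[i + 1L]) { d <- i; break }
    }
  }
  if (is.na(d)) d <- which.min(ami)
  list(delay = as.integer(d), delay_s = as.integer(d) * mean(x) / 1000,
       ami = ami)
}

# Accept rri_series or numeric vector everywhere in the metric modules.
as_numeric_series <- function(x) {
  if (inherits(x, "rri_series")) x$intervals else as.numeric(x)
}
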
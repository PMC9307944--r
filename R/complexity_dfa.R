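# Detrended fluctuation analysis, monofractal and multifractal.

# Mean squared residuals of order-1 polynomial detrending in non-overlapping
# windows of the integrated profile, taken from both ends of the series.
.dfa_window_f2 <- function(profile, s) {
  n <- length(profile)
  nw <- n %/% s
  if (nw < 1L) return(numeric(0))
  tt <- seq_len(s)
  X <- cbind(1, tt)
  # hat-matrix-free residuals via qr once per scale
  qrX <- qr(X)
  f2 <- function(seg) {
    r <- qr.resid(qrX, seg)
    mean(r^2)
  }
  starts <- c((seq_len(nw) - 1L) * s + 1L, n - (seq_len(nw)) * s + 1L)
  vapply(starts, function(st) f2(profile[st:(st + s - 1L)]), numeric(1))
}

#' Detrended fluctuation analysis
#'
#' Order-1 DFA: the mean-removed series is integrated, detrended in
#' non-overlapping windows (taken from both ends), and the fluctuation
#' function `F(s)` is fitted against scale in log-log coordinates. The
#' short-term exponent alpha1 uses scales 4-16 beats and the long-term
#' alpha2 16-64 beats by default.
#'
#' @param x Numeric series (e.g. RRI segment).
#' @param scales Integer vector of window sizes.
#' @return List with `alpha` (slope), `scales`, `F` (fluctuation function).
#'   `alpha` is `NA` when fewer than 3 scales fit in the data.
#' @export
compute_dfa <- function(x, scales = dfa_scales(4, 16)) {
  x <- as_numeric_series(x)
  n <- length(x)
  scales <- sort(unique(as.integer(scales)))
  scales <- scales[scales >= 4]
  # data contract: the series must cover 4x the largest requested scale
  if (length(scales) < 3L || n < 4L * max(scales) || stats::sd(x) == 0) {
    return(list(alpha = NA_real_, scales = scales, F = numeric(0)))
  }
  prof <- cumsum(x - mean(x))
  Fs <- vapply(scales, function(s) {
    sqrt(mean(.dfa_window_f2(prof, s)))
  }, numeric(1))
  keep <- Fs > 0
  if (sum(keep) < 3L) {
    return(list(alpha = NA_real_, scales = scales, F = Fs))
  }
  alpha <- stats::coef(stats::lm(log(Fs[keep]) ~ log(scales[keep])))[[2]]
  list(alpha = alpha, scales = scales, F = Fs)
}

#' Log-spaced DFA scales within a range
#'
#' @param lo,hi Scale range in beats.
#' @param n Number of scales (default 8).
#' @return Integer scales.
#' @export
dfa_scales <- function(lo, hi, n = 8L) {
  unique(round(exp(seq(log(lo), log(hi), length.out = n))))
}

#' Multifractal detrended fluctuation analysis
#'
#' q-order fluctuation functions over the given scales yield the
#' generalised Hurst exponents `h(q)`; the singularity spectrum
#' `(alpha, f(alpha))` follows by Legendre transform
#' (`alpha = h(q) + q h'(q)`, `f = q (alpha - h(q)) + 1`). Summary
#' features: Width `= max(alpha) - min(alpha)`, Peak (alpha at maximal f),
#' Mean (mean alpha), Max (maximal f), Delta `= h(q_min) - h(q_max)`,
#' Asymmetry (left-branch width minus right-branch width about the peak),
#' Fluctuation (mean of F(s) at q = 2 over the scales) and Increment
#' (mean absolute step of the h(q) curve).
#'
#' @param x Numeric series.
#' @param q_list Moment orders (default -5..5 without 0).
#' @param scales Integer window sizes.
#' @return List of the named features plus `h_q`, `alpha`, `f_alpha`;
#'   features are `NA` when the spectrum does not converge.
#' @export
compute_mfdfa <- function(x, q_list = setdiff(-5:5, 0),
                          scales = dfa_scales(4, 16)) {
  x <- as_numeric_series(x)
  n <- length(x)
  scales <- sort(unique(as.integer(scales)))
  scales <- scales[scales >= 4]
  empty <- list(Width = NA_real_, Peak = NA_real_, Mean = NA_real_,
                Max = NA_real_, Delta = NA_real_, Asymmetry = NA_real_,
                Fluctuation = NA_real_, Increment = NA_real_,
                h_q = NULL, alpha = NULL, f_alpha = NULL)
  if (length(scales) < 3L || n < 4L * max(scales) ||
      stats::sd(x) == 0) return(empty)
  q_list <- sort(q_list[q_list != 0])
  prof <- cumsum(x - mean(x))
  f2 <- lapply(scales, function(s) .dfa_window_f2(prof, s))
  # F_q(s) matrix: rows q, cols scales
  Fq <- vapply(seq_along(scales), function(si) {
    v <- f2[[si]]
    v <- v[v > 0]
    if (!length(v)) return(rep(NA_real_, length(q_list)))
    vapply(q_list, function(q) mean(v^(q / 2))^(1 / q), numeric(1))
  }, numeric(length(q_list)))
  Fq <- matrix(Fq, nrow = length(q_list))
  if (any(!is.finite(Fq))) return(empty)
  ls <- log(scales)
  h_q <- apply(Fq, 1L, function(row) {
    stats::coef(stats::lm(log(row) ~ ls))[[2]]
  })
  # Legendre transform with centered numeric derivative of tau(q)=q h(q)-1
  tau <- q_list * h_q - 1
  alpha <- numeric(length(q_list))
  for (i in seq_along(q_list)) {
    if (i == 1L) {
      alpha[i] <- (tau[2] - tau[1]) / (q_list[2] - q_list[1])
    } else if (i == length(q_list)) {
      alpha[i] <- (tau[i] - tau[i - 1]) / (q_list[i] - q_list[i - 1])
    } else {
      alpha[i] <- (tau[i + 1] - tau[i - 1]) / (q_list[i + 1] - q_list[i - 1])
    }
  }
  f_alpha <- q_list * alpha - tau
  # convergence guard: h(q) should be (weakly) non-increasing
  if (any(diff(h_q) > 0.2)) return(empty)
  peak_i <- which.max(f_alpha)
  i2 <- which(q_list == 2L)
  fluct <- if (length(i2)) mean(Fq[i2, ]) else NA_real_
  list(
    Width = max(alpha) - min(alpha),
    Peak = alpha[peak_i],
    Mean = mean(alpha),
    Max = f_alpha[peak_i],
    Delta = h_q[1] - h_q[length(h_q)],
    Asymmetry = (max(alpha) - alpha[peak_i]) - (alpha[peak_i] - min(alpha)),
    Fluctuation = fluct,
    Increment = mean(abs(diff(h_q))),
    h_q = h_q, alpha = alpha, f_alpha = f_alpha
  )
}
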
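# Time-domain HRV metrics on one RRI segment.

# Midpoint-interpolation percentile (the convention used throughout the
# package): the average of the two order statistics straddling the target
# rank, i.e. numpy's interpolation='midpoint'.
percentile_midpoint <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p / 100 + 1
  lo <- floor(h); hi <- ceiling(h)
  if (lo == hi) x[lo] else (x[lo] + x[hi]) / 2
}

# Histogram of intervals at the conventional 1/128 s bin width, aligned to
# multiples of the bin width.
.rri_hist <- function(x, binwidth = 1000 / 128) {
  lo <- floor(min(x) / binwidth) * binwidth
  hi <- ceiling(max(x) / binwidth) * binwidth
  if (hi <= lo) hi <- lo + binwidth
  br <- seq(lo, hi, by = binwidth)
  if (br[length(br)] < max(x)) br <- c(br, br[length(br)] + binwidth)
  h <- graphics::hist(x, breaks = br, plot = FALSE)
  list(counts = h$counts, mids = h$mids, binwidth = binwidth)
}

# Least-squares triangular interpolation of the interval histogram:
# baseline width of the best-fitting triangle with apex at the modal bin.
.tinn <- function(x, binwidth = 1000 / 128) {
  h <- .rri_hist(x, binwidth)
  cnt <- h$counts; mids <- h$mids
  k <- length(cnt)
  peak <- which.max(cnt)
  Y <- cnt[peak]
  if (k < 3L || Y == 0) return(NA_real_)
  best <- Inf; bestN <- mids[peak]; bestM <- mids[peak]
  for (iN in seq_len(peak)) {
    for (iM in peak:k) {
      tri <- numeric(k)
      if (iN < peak) {
        up <- iN:peak
        tri[up] <- Y * (mids[up] - mids[iN]) / (mids[peak] - mids[iN])
      }
      tri[peak] <- Y
      if (iM > peak) {
        dn <- peak:iM
        tri[dn] <- Y * (mids[iM] - mids[dn]) / (mids[iM] - mids[peak])
      }
      err <- sum((cnt - tri)^2)
      if (err < best) { best <- err; bestN <- mids[iN]; bestM <- mids[iM] }
    }
  }
  bestM - bestN
}

# SD of sub-segment means (SDANN) and mean of sub-segment SDs (SDNNI) for
# n-minute sub-segments; NA when fewer than 2 full sub-segments fit.
.sdann_sdnni <- function(x, minutes) {
  win_ms <- minutes * 60 * 1000
  onset <- c(0, cumsum(x))[-(length(x) + 1L)]
  bin <- floor(onset / win_ms)
  total <- sum(x)
  full <- seq_len(floor(total / win_ms)) - 1L
  if (length(full) < 2L) return(c(sdann = NA_real_, sdnni = NA_real_))
  means <- vapply(full, function(b) mean(x[bin == b]), numeric(1))
  sds <- vapply(full, function(b) {
    v <- x[bin == b]
    if (length(v) < 2L) NA_real_ else stats::sd(v)
  }, numeric(1))
  c(sdann = stats::sd(means), sdnni = mean(sds, na.rm = TRUE))
}

#' Time-domain HRV metrics
#'
#' Computes the full time-domain family on one RRI segment: dispersion
#' statistics of the intervals (SDNN, MadNN, IQRNN, percentiles),
#' successive-difference statistics (RMSSD, SDSD, pNN50, pNN20),
#' normalised variants (CVNN, CVSD, MCVNN), the geometric histogram
#' measures (HTI, TINN at 1/128 s bin width) and the multi-window
#' SDANN/SDNNI trio at 1, 2 and 5 minutes. SDs are sample SDs (ddof 1);
#' percentiles use midpoint interpolation.
#'
#' @param rri An `rri_series` or numeric vector of intervals (ms).
#' @param hist_binwidth Histogram bin width in ms for HTI/TINN
#'   (default 1000/128).
#' @return Named list of the 24 time-domain metrics; all `NA` (with a
#'   `reason` attribute) when fewer than 2 intervals are supplied.
#' @export
compute_time_domain <- function(rri, hist_binwidth = 1000 / 128) {
  x <- as_numeric_series(rri)
  nm <- c("MeanNN", "SDNN", "RMSSD", "SDSD", "CVNN", "CVSD", "MedianNN",
          "MadNN", "MCVNN", "IQRNN", "pNN50", "pNN20", "TINN", "HTI",
          "SDANN1", "SDNNI1", "SDANN2", "SDNNI2", "SDANN5", "SDNNI5",
          "Prc20NN", "Prc80NN", "MinNN", "MaxNN")
  if (length(x) < 2L) {
    out <- stats::setNames(as.list(rep(NA_real_, length(nm))), nm)
    attr(out, "reason") <- "too few intervals"
    return(out)
  }
  d <- diff(x)
  mean_nn <- mean(x)
  sdnn <- stats::sd(x)
  rmssd <- sqrt(mean(d^2))
  out <- list(
    MeanNN = mean_nn,
    SDNN = sdnn,
    RMSSD = rmssd,
    SDSD = if (length(d) >= 2L) stats::sd(d) else NA_real_,
    CVNN = sdnn / mean_nn,
    CVSD = rmssd / mean_nn,
    MedianNN = stats::median(x),
    MadNN = stats::mad(x),
    MCVNN = stats::mad(x) / stats::median(x),
    IQRNN = percentile_midpoint(x, 75) - percentile_midpoint(x, 25),
    pNN50 = 100 * mean(abs(d) > 50),
    pNN20 = 100 * mean(abs(d) > 20),
    TINN = .tinn(x, hist_binwidth),
    HTI = length(x) / max(.rri_hist(x, hist_binwidth)$counts),
    Prc20NN = percentile_midpoint(x, 20),
    Prc80NN = percentile_midpoint(x, 80),
    MinNN = min(x),
    MaxNN = max(x)
  )
  for (mn in c(1, 2, 5)) {
    ss <- .sdann_sdnni(x, mn)
    out[[paste0("SDANN", mn)]] <- ss[["sdann"]]
    out[[paste0("SDNNI", mn)]] <- ss[["sdnni"]]
  }
  out[nm]
}
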
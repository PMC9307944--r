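# Frequency-domain HRV metrics: Welch PSD of the interpolated heart-period
# signal and band-power integration.

#' Default HRV frequency bands
#'
#' Conventional Task-Force edges: ULF [0, 0.0033), VLF [0.0033, 0.04),
#' LF [0.04, 0.15), HF [0.15, 0.4), VHF [0.4, 0.5) Hz.
#'
#' @return A data.frame with columns `name`, `lo`, `hi` (Hz).
#' @export
default_bands <- function() {
  data.frame(
    name = c("ULF", "VLF", "LF", "HF", "VHF"),
    lo = c(0, 0.0033, 0.04, 0.15, 0.4),
    hi = c(0.0033, 0.04, 0.15, 0.4, 0.5),
    stringsAsFactors = FALSE
  )
}

validate_bands <- function(bands) {
  stopifnot(all(c("name", "lo", "hi") %in% names(bands)))
  stopifnot(all(bands$lo < bands$hi), all(bands$lo >= 0))
  o <- order(bands$lo)
  bands <- bands[o, ]
  if (nrow(bands) > 1L &&
      any(bands$lo[-1L] < bands$hi[-nrow(bands)] - 1e-12)) {
    stop("bands must be non-overlapping")
  }
  bands
}

#' Welch power spectral density
#'
#' One-sided Welch estimate: mean-removed signal, Hann-windowed segments
#' with 50% overlap, periodograms averaged and scaled so that the integral
#' of the PSD over frequency equals the signal variance (Parseval).
#'
#' @param x Uniformly sampled signal.
#' @param fs Sampling rate in Hz.
#' @param nperseg Segment length (default `min(256, length(x))`).
#' @return List with `freqs` (Hz), `power` (units^2/Hz) of class
#'   `spectral_density`.
#' @export
welch_psd <- function(x, fs, nperseg = min(256L, length(x))) {
  n <- length(x)
  if (n < 64L) stop("insufficient data for PSD: need >= 64 samples")
  x <- x - mean(x)
  nperseg <- min(nperseg, n)
  step <- max(1L, nperseg %/% 2L)
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))  # Hann
  scale <- fs * sum(w^2)
  nfreq <- nperseg %/% 2L + 1L
  acc <- numeric(nfreq)
  for (st in starts) {
    seg <- x[st:(st + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(stats::fft(seg))[seq_len(nfreq)]^2 / scale
    acc <- acc + p
  }
  p <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist for even nperseg)
  dbl <- rep(2, nfreq); dbl[1L] <- 1
  if (nperseg %% 2L == 0L) dbl[nfreq] <- 1
  p <- p * dbl
  structure(list(freqs = (seq_len(nfreq) - 1L) * fs / nperseg,
                 power = p, method = "welch_hann_50"),
            class = "spectral_density")
}

#' Estimate the RRI power spectral density
#'
#' Interpolates the RRI onto a uniform 4 Hz grid (see
#' [interpolate_rri()]) and applies Welch averaging. The integral of the
#' result approximates the interval variance (ms^2).
#'
#' @param rri An `rri_series`.
#' @param peaks The matching `peak_series`.
#' @param fs Interpolation rate in Hz (default 4).
#' @param nperseg Welch segment length (default 256 samples).
#' @return A `spectral_density` (power in ms^2/Hz).
#' @export
estimate_psd <- function(rri, peaks, fs = 4, nperseg = 256L) {
  sig <- interpolate_rri(rri, peaks, target_rate = fs)
  welch_psd(sig$signal, sig$rate, nperseg)
}

#' @export
print.spectral_density <- function(x, ...) {
  cat(sprintf("<spectral_density> %d bins, 0-%.3g Hz (%s)\n",
              length(x$freqs), max(x$freqs), x$method))
  invisible(x)
}

# Integral of the PSD over [lo, hi) by the rectangle rule on the FFT grid.
band_power <- function(psd, lo, hi) {
  df <- if (length(psd$freqs) > 1L) psd$freqs[2] - psd$freqs[1] else 0
  sel <- psd$freqs >= lo & psd$freqs < hi
  sum(psd$power[sel]) * df
}

#' Frequency-domain HRV metrics
#'
#' Integrates the PSD over the configured bands; LFn/HFn are normalised by
#' the total power over all bands (a LF+HF denominator is available via
#' `normalize = "lf_hf"`), LFHF is the LF/HF ratio and LnHF the natural
#' log of HF. TP is the total power over all bands.
#'
#' @param psd A `spectral_density` (e.g. from [estimate_psd()]).
#' @param bands Band definition data.frame (default [default_bands()]).
#' @param normalize Denominator for LFn/HFn: `"total"` (default) or
#'   `"lf_hf"`.
#' @return Named list: per-band powers (ms^2), `TP`, `LFHF`, `LFn`, `HFn`,
#'   `LnHF`. `LFHF`/`LnHF` are `NA` when HF is 0.
#' @export
compute_frequency_domain <- function(psd, bands = default_bands(),
                                     normalize = c("total", "lf_hf")) {
  normalize <- match.arg(normalize)
  bands <- validate_bands(bands)
  pw <- stats::setNames(
    vapply(seq_len(nrow(bands)),
           function(i) band_power(psd, bands$lo[i], bands$hi[i]),
           numeric(1)),
    bands$name)
  total <- sum(pw)
  lf <- unname(pw["LF"]); hf <- unname(pw["HF"])
  denom <- if (normalize == "total") total else lf + hf
  out <- as.list(pw)
  out$TP <- total
  out$LFHF <- if (!is.na(hf) && hf > 0) lf / hf else NA_real_
  out$LFn <- if (denom > 0) lf / denom else NA_real_
  out$HFn <- if (denom > 0) hf / denom else NA_real_
  out$LnHF <- if (!is.na(hf) && hf > 0) log(hf) else NA_real_
  out
}
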
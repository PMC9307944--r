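#' Construct a peak series
#'
#' A peak series holds strictly increasing R-peak sample indices together
#' with the sampling rate of the acquisition device. It is the raw input
#' unit of the pipeline; everything downstream derives from it.
#'
#' @param times Numeric vector of R-peak sample indices (0-based or
#'   arbitrary-origin; only differences matter). Must be non-negative.
#' @param sampling_rate Sampling rate in Hz (default 1000).
#' @param stream_label Free-text label for the stream (e.g. "fetal",
#'   "maternal").
#' @return An object of class `peak_series`.
#' @export
peak_series <- function(times, sampling_rate = 1000, stream_label = "") {
  times <- as.numeric(times)
  if (length(times) == 0L) stop("insufficient beats: empty peak series")
  if (any(!is.finite(times))) stop("peak times must be finite")
  if (any(times < 0)) stop("peak times must be >= 0")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0) {
    stop("sampling_rate must be a single positive number")
  }
  structure(
    list(times = times, sampling_rate = sampling_rate,
         stream_label = as.character(stream_label)),
    class = "peak_series"
  )
}

#' @export
print.peak_series <- function(x, ...) {
  cat(sprintf("<peak_series> %d peaks @ %g Hz%s\n", length(x$times),
              x$sampling_rate,
              if (nzchar(x$stream_label)) paste0(" [", x$stream_label, "]")
              else ""))
  invisible(x)
}

#' @export
length.peak_series <- function(x) length(x$times)

#' Construct an RR-interval series
#'
#' Successive inter-beat intervals in milliseconds. `t_start` gives the
#' onset (seconds from the first beat) of each interval; intervals are
#' half-open `[peak_i, peak_{i+1})`.
#'
#' @param intervals Numeric vector of RR intervals in ms; all finite, > 0.
#' @param t_start Optional onset times (s); computed from the cumulative
#'   sum when omitted.
#' @return An object of class `rri_series`.
#' @export
rri_series <- function(intervals, t_start = NULL) {
  intervals <- as.numeric(intervals)
  if (length(intervals) == 0L) stop("insufficient beats: empty RRI series")
  if (any(!is.finite(intervals)) || any(intervals <= 0)) {
    stop("RR intervals must be finite and > 0")
  }
  if (is.null(t_start)) {
    t_start <- c(0, cumsum(intervals[-length(intervals)])) / 1000
  }
  stopifnot(length(t_start) == length(intervals))
  structure(list(intervals = intervals, t_start = as.numeric(t_start)),
            class = "rri_series")
}

#' @export
print.rri_series <- function(x, ...) {
  cat(sprintf("<rri_series> %d intervals, mean %.1f ms, span %.1f s\n",
              length(x$intervals), mean(x$intervals),
              sum(x$intervals) / 1000))
  invisible(x)
}

#' @export
length.rri_series <- function(x) length(x$intervals)

# Coerce plain numeric input to the container without re-validating class
# objects. Internal.
as_peak_series <- function(x, sampling_rate = 1000) {
  if (inherits(x, "peak_series")) x else peak_series(x, sampling_rate)
}

as_rri_series <- function(x) {
  if (inherits(x, "rri_series")) x else rri_series(x)
}

#' Trim trailing zeros from a peak series
#'
#' Fixed-length acquisition buffers pad the peak channel with zeros; this
#' removes the trailing zero block while leaving leading/interior values
#' untouched.
#'
#' @param peaks A `peak_series` or numeric vector of sample indices.
#' @param sampling_rate Sampling rate used when `peaks` is a bare vector.
#' @return A `peak_series` without the trailing zeros.
#' @export
trim_trailing_zeros <- function(peaks, sampling_rate = 1000) {
  p <- as_peak_series(peaks, sampling_rate)
  t <- p$times
  nz <- which(t != 0)
  last <- if (length(nz)) max(nz) else 0L
  t <- t[seq_len(last)]
  if (length(t) < 2L) stop("insufficient beats after trailing-zero trim")
  peak_series(t, p$sampling_rate, p$stream_label)
}

#' Convert peak times to RR intervals
#'
#' Interval i = (times[i+1] - times[i]) / sampling_rate * 1000, in ms.
#'
#' @param peaks A `peak_series` (or numeric vector) of strictly increasing
#'   peak sample indices.
#' @param sampling_rate Sampling rate used when `peaks` is a bare vector.
#' @return An `rri_series` of length `length(peaks) - 1`.
#' @export
peaks_to_rri <- function(peaks, sampling_rate = 1000) {
  p <- as_peak_series(peaks, sampling_rate)
  if (length(p$times) < 2L) stop("insufficient beats: need >= 2 peaks")
  d <- diff(p$times)
  if (any(d <= 0)) stop("non-monotone peaks: times must be strictly increasing")
  rri_series(d / p$sampling_rate * 1000)
}

#' Interpolate RR intervals onto a uniform time grid
#'
#' Produces a regularly sampled heart-period signal by linear interpolation
#' of the interval values anchored at the second-through-last peak times
#' (each interval is anchored at the beat that closes it). Values outside
#' the anchor range are held constant at the nearest anchor. The requested
#' rate is floored at 10 Hz.
#'
#' @param rri An `rri_series` (ms).
#' @param peaks The matching `peak_series` (one more element than `rri`).
#' @param target_rate Requested output rate in Hz; values below 10 are
#'   promoted to 10.
#' @return A list with `signal` (ms), `rate` (Hz actually used) and
#'   `t` (grid times in seconds from the first peak).
#' @export
interpolate_rri <- function(rri, peaks, target_rate = 10) {
  r <- as_rri_series(rri)
  p <- as_peak_series(peaks)
  if (length(p$times) < 3L) stop("insufficient beats: need >= 3 peaks")
  stopifnot(length(r$intervals) == length(p$times) - 1L)
  if (target_rate < 10) target_rate <- 10
  t_anchor <- (p$times[-1L] - p$times[1L]) / p$sampling_rate   # seconds
  n_out <- round(t_anchor[length(t_anchor)] * target_rate)
  t_new <- seq(0, by = 1 / target_rate, length.out = n_out)
  sig <- stats::approx(t_anchor, r$intervals, xout = t_new, rule = 2)$y
  list(signal = sig, rate = target_rate, t = t_new)
}

#' Physiological artifact-bound profiles
#'
#' Default inter-beat interval bounds per subject profile: the fetal
#' profile allows 0.33-0.75 s (80-180 bpm) and the maternal/adult profile
#' 0.4-1.5 s (40-150 bpm). The equivalent heart-rate limits are
#' `60 / interval` bpm.
#'
#' @return Data frame with columns profile, interval_min, interval_max
#'   (seconds), bpm_min, bpm_max.
#' @export
artifact_profiles <- function() {
  p <- data.frame(
    profile = c("fetal", "maternal"),
    interval_min = c(0.33, 0.4),
    interval_max = c(0.75, 1.5),
    stringsAsFactors = FALSE
  )
  p$bpm_min <- 60 / p$interval_max
  p$bpm_max <- 60 / p$interval_min
  p
}

# Running local median of in-bound intervals around position i. Used by the
# artifact corrector as its reference beat length.
local_median <- function(x, i, ok, half = 5) {
  lo <- max(1L, i - half); hi <- min(length(x), i + half)
  w <- x[lo:hi][ok[lo:hi]]
  if (!length(w)) w <- x[ok]
  if (!length(w)) return(NA_real_)
  stats::median(w)
}

#' Rule-based artifact correction on peaks
#'
#' Enforces physiological interval bounds on a trimmed, increasing peak
#' series using deterministic rules applied in a single left-to-right pass:
#' \itemize{
#'   \item an adjacent short/long pair whose sum is within 25% of twice the
#'     local median is treated as one ectopic beat and replaced by two
#'     equal interpolants (`ectopic_interpolated`);
#'   \item an interval above `interval_max` is split into
#'     `k = round(interval / local median)` equal parts, i.e. missed beats
#'     are re-inserted (`missed_inserted`);
#'   \item an interval below `interval_min` is merged with its neighbour,
#'     i.e. a spuriously detected extra beat is removed (`extra_merged`).
#' }
#' All rules conserve total recording duration exactly. The pass is single
#' (no fixed-point iteration) but re-examines a modified position, so the
#' result is idempotent: re-running on corrected output yields zero
#' corrections.
#'
#' @param peaks A `peak_series` (trimmed, strictly increasing).
#' @param interval_min,interval_max Physiological interval bounds in
#'   seconds (defaults: adult profile 0.4-1.5 s; use 0.33-0.75 s for the
#'   fetal profile).
#' @return A list with `peaks` (corrected `peak_series`), `rri` (corrected
#'   `rri_series`) and `report` (an `artifact_report`).
#' @export
correct_artifacts <- function(peaks, interval_min = 0.4, interval_max = 1.5) {
  p <- as_peak_series(peaks)
  if (!(interval_min > 0 && interval_min < interval_max)) {
    stop("need 0 < interval_min < interval_max")
  }
  d0 <- diff(p$times)
  if (length(d0) < 1L) stop("insufficient beats: need >= 2 peaks")
  if (any(d0 <= 0)) stop("non-monotone peaks")
  iv <- d0 / p$sampling_rate * 1000      # ms
  min_ms <- interval_min * 1000
  max_ms <- interval_max * 1000
  ok0 <- iv >= min_ms & iv <= max_ms
  if (!any(ok0)) stop("uncorrectable series: bounds exclude all intervals")

  out <- numeric(0)
  rows <- list()
  add_row <- function(index, class, before, after) {
    rows[[length(rows) + 1L]] <<- data.frame(
      index = index, class = class, before_ms = before, after_ms = after,
      stringsAsFactors = FALSE)
  }
  work <- iv
  idx_in <- seq_along(iv)   # provenance: input index of each working interval
  i <- 1L
  guard <- 0L
  while (i <= length(work)) {
    guard <- guard + 1L
    if (guard > 10L * length(iv) + 100L) {
      stop("uncorrectable series: correction did not terminate")
    }
    x <- work[i]
    ok <- work >= min_ms & work <= max_ms
    med <- local_median(work, i, ok)
    if (is.na(med)) med <- stats::median(work)
    if (x >= min_ms && x <= max_ms) { out <- c(out, x); i <- i + 1L; next }
    nxt <- if (i < length(work)) work[i + 1L] else NA_real_
    # ectopic: short+long (either order) pair summing to ~2 local beats
    if (!is.na(nxt) &&
        ((x < min_ms && nxt > max_ms) || (x > max_ms && nxt < min_ms)) &&
        abs(x + nxt - 2 * med) <= 0.25 * 2 * med) {
      rep_val <- (x + nxt) / 2
      add_row(idx_in[i], "ectopic_interpolated", x, rep_val)
      add_row(idx_in[i + 1L], "ectopic_interpolated", nxt, rep_val)
      work <- c(work[seq_len(i - 1L)], rep_val, rep_val,
                if (i + 2L <= length(work)) work[(i + 2L):length(work)])
      next                              # re-examine replacement
    }
    if (x > max_ms) {                   # missed beat(s): split
      k <- round(x / med)
      k_lo <- ceiling(x / max_ms); k_hi <- floor(x / min_ms)
      k <- max(2, k)
      k <- min(max(k, k_lo), k_hi)
      if (k_lo > k_hi || k < 2) {
        stop("uncorrectable series: long interval cannot be split within bounds")
      }
      part <- x / k
      add_row(idx_in[i], "missed_inserted", x, part)
      work <- c(work[seq_len(i - 1L)], rep(part, k),
                if (i + 1L <= length(work)) work[(i + 1L):length(work)])
      idx_in <- c(idx_in[seq_len(i - 1L)], rep(idx_in[i], k),
                  if (i + 1L <= length(idx_in)) idx_in[(i + 1L):length(idx_in)])
      next
    }
    # too short: merge with following (previous when last)
    if (!is.na(nxt)) {
      merged <- x + nxt
      add_row(idx_in[i], "extra_merged", x, merged)
      work <- c(work[seq_len(i - 1L)], merged,
                if (i + 2L <= length(work)) work[(i + 2L):length(work)])
      idx_in <- c(idx_in[seq_len(i - 1L)], idx_in[i],
                  if (i + 2L <= length(idx_in)) idx_in[(i + 2L):length(idx_in)])
      next                              # merged value re-examined at i
    }
    if (length(out)) {                  # last interval short: merge backwards
      merged <- out[length(out)] + x
      add_row(idx_in[i], "extra_merged", x, merged)
      if (merged > max_ms) {
        k <- max(2, round(merged / med))
        out <- c(out[-length(out)], rep(merged / k, k))
      } else {
        out[length(out)] <- merged
      }
      i <- i + 1L
      next
    }
    stop("uncorrectable series: single out-of-bounds interval")
  }
  report <- structure(
    list(n_input_beats = length(p$times),
         corrections = if (length(rows)) do.call(rbind, rows) else
           data.frame(index = integer(), class = character(),
                      before_ms = numeric(), after_ms = numeric(),
                      stringsAsFactors = FALSE),
         parameters = list(interval_min = interval_min,
                           interval_max = interval_max,
                           method = "rule_based_single_pass")),
    class = "artifact_report")
  new_times <- p$times[1L] + c(0, cumsum(out * p$sampling_rate / 1000))
  list(peaks = peak_series(new_times, p$sampling_rate, p$stream_label),
       rri = rri_series(out),
       report = report)
}

#' @export
print.artifact_report <- function(x, ...) {
  cat(sprintf("<artifact_report> %d input beats, %d corrections (%s)\n",
              x$n_input_beats, nrow(x$corrections), x$parameters$method))
  if (nrow(x$corrections)) print(table(x$corrections$class))
  invisible(x)
}

#' Serialize an artifact report to a data frame
#'
#' One row per corrected input interval with the audit-log schema
#' (SubjectID, index, class, before_ms, after_ms).
#'
#' @param report An `artifact_report`.
#' @param subject_id Subject identifier column value.
#' @return A data.frame in audit-log schema.
#' @export
artifact_log_frame <- function(report, subject_id = "") {
  k <- report$corrections
  data.frame(SubjectID = rep(subject_id, nrow(k)), k,
             stringsAsFactors = FALSE)
}

# np.array_split semantics: n chunks, the first (len %% n) one element longer.
array_split_sizes <- function(len, n) {
  n <- max(1L, as.integer(n))
  base <- len %/% n
  extra <- len %% n
  c(rep(base + 1L, extra), rep(base, n - extra))
}

#' Segment a recording into fixed-duration analysis windows
#'
#' The number of segments follows the divider formula: total duration in
#' seconds (from time origin to the last peak) divided by the window length;
#' beats are then partitioned into that many contiguous near-equal-count
#' chunks (`numpy.array_split` semantics), the default mode. A strict
#' time-based windowing mode cuts at exact multiples of the window instead.
#'
#' @param peaks A `peak_series`.
#' @param rri The matching `rri_series` (length `length(peaks) - 1`).
#' @param window_minutes Window length in minutes (default 5).
#' @param mode `"beat_count"` (default, divider formula) or `"time"`.
#' @return An object of class `segment_set`: list with `segments` (each a
#'   list with `peaks`, `rri`), `window_minutes`, `last_partial`.
#' @export
segment_series <- function(peaks, rri, window_minutes = 5,
                           mode = c("beat_count", "time")) {
  mode <- match.arg(mode)
  p <- as_peak_series(peaks)
  r <- as_rri_series(rri)
  stopifnot(length(r$intervals) == length(p$times) - 1L)
  if (window_minutes <= 0) stop("window_minutes must be > 0")
  duration_s <- p$times[length(p$times)] / p$sampling_rate
  if (duration_s <= 0) stop("series spans no time")
  window_ms <- window_minutes * 60 * 1000

  if (mode == "beat_count") {
    divider <- duration_s / (60 * window_minutes)
    n_seg <- max(1L, as.integer(round(divider)))
    sizes_r <- array_split_sizes(length(r$intervals), n_seg)
    ends <- cumsum(sizes_r)
    starts <- c(1L, head(ends, -1L) + 1L)
    segs <- lapply(seq_len(n_seg), function(k) {
      if (sizes_r[k] == 0L) return(NULL)
      ivs <- r$intervals[starts[k]:ends[k]]
      pk <- p$times[starts[k]:(ends[k] + 1L)]
      list(peaks = peak_series(pk, p$sampling_rate, p$stream_label),
           rri = rri_series(ivs))
    })
    segs <- Filter(Negate(is.null), segs)
  } else {
    onset_ms <- c(0, cumsum(r$intervals))[-(length(r$intervals) + 1L)]
    bin <- pmin(floor(onset_ms / window_ms),
                ceiling(sum(r$intervals) / window_ms) - 1)
    segs <- lapply(split(seq_along(r$intervals), bin), function(idx) {
      list(peaks = peak_series(p$times[c(idx, max(idx) + 1L)],
                               p$sampling_rate, p$stream_label),
           rri = rri_series(r$intervals[idx]))
    })
    names(segs) <- NULL
  }
  last_dur <- sum(segs[[length(segs)]]$rri$intervals)
  structure(list(segments = segs, window_minutes = window_minutes,
                 last_partial = last_dur < window_ms - 1e-9),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %d segments of %g min%s\n", length(x$segments),
              x$window_minutes,
              if (x$last_partial) " (last partial)" else ""))
  invisible(x)
}

#' @export
length.segment_set <- function(x) length(x$segments)

#' Read a peak series from delimited text
#'
#' Expects one column of sample indices (no header by default; a single
#' header line is auto-skipped when non-numeric).
#'
#' @param path File path (CSV or whitespace-delimited).
#' @param sampling_rate Sampling rate in Hz.
#' @param stream_label Stream label for the series.
#' @param column Column index to read (default 1).
#' @return A `peak_series`.
#' @export
read_peaks_csv <- function(path, sampling_rate = 1000, stream_label = "",
                           column = 1L) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  probe <- suppressWarnings(as.numeric(strsplit(first, if (sep == ",") "," else
                                                "[[:space:]]+")[[1]][column]))
  df <- utils::read.table(path, sep = sep, header = is.na(probe))
  peak_series(df[[column]], sampling_rate, stream_label)
}

#' Read a peak series from a MATLAB .mat container
#'
#' Extracts one row of a named matrix variable (e.g. row 5 of
#' `fetal_Rpeaks`). No MAT reader ships with this R installation, so the
#' extraction is delegated to the Python `scipy.io` of the same
#' environment; an informative error is raised if `python` is unavailable.
#'
#' @param path Path to the .mat file.
#' @param variable Variable name inside the container.
#' @param row 1-based row index of the matrix to extract.
#' @param sampling_rate Sampling rate in Hz.
#' @param stream_label Stream label.
#' @return A `peak_series`.
#' @export
read_peaks_mat <- function(path, variable, row = 1L, sampling_rate = 1000,
                           stream_label = "") {
  py <- Sys.which("python")
  if (!nzchar(py)) {
    stop("read_peaks_mat requires a python with scipy on PATH; ",
         "convert the file to CSV instead")
  }
  code <- sprintf(
    "import scipy.io,sys; m=scipy.io.loadmat(%s); v=m[%s]; print('\\n'.join(repr(float(x)) for x in v[%d]))",
    deparse(path), deparse(variable), as.integer(row) - 1L)
  vals <- suppressWarnings(system2(py, c("-c", shQuote(code)), stdout = TRUE))
  st <- attr(vals, "status")
  if (!is.null(st) && st != 0) stop("python scipy.io extraction failed")
  peak_series(as.numeric(vals), sampling_rate, stream_label)
}
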
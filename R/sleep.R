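# Sleep-stage label handling and the metric/stage correlation analysis.

.legal_stages <- c(0L, 1L, 2L, 3L, 5L)

#' Parse a labeled-sleep file
#'
#' Parses polysomnography label content in the format
#' `"<seconds since start> <stage>"` per line, with stages coded
#' wake = 0, N1 = 1, N2 = 2, N3 = 3, REM = 5. The epoch length is
#' inferred as the modal timestamp difference.
#'
#' @param x Path to a label file, or a character vector of label lines.
#' @return An object of class `sleep_labels`: list with `t` (s), `stage`
#'   (integer), `epoch_s`.
#' @export
parse_sleep_labels <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  lines <- trimws(lines)
  keep <- nzchar(lines)
  lines <- lines[keep]
  if (!length(lines)) stop("no label lines to parse")
  parts <- strsplit(lines, "[[:space:]]+")
  bad_shape <- which(vapply(parts, length, integer(1)) != 2L)
  if (length(bad_shape)) {
    stop("malformed label line ", bad_shape[1], ": '", lines[bad_shape[1]],
         "'")
  }
  t <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
  s <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  bad_num <- which(is.na(t) | is.na(s))
  if (length(bad_num)) {
    stop("non-numeric label line ", bad_num[1], ": '", lines[bad_num[1]],
         "'")
  }
  bad_stage <- which(!(s %in% .legal_stages))
  if (length(bad_stage)) {
    stop("illegal stage code ", s[bad_stage[1]], " at line ", bad_stage[1],
         " (legal: 0,1,2,3,5)")
  }
  if (is.unsorted(t)) stop("label timestamps must be non-decreasing")
  dt <- diff(t)
  epoch <- if (length(dt)) {
    tb <- table(dt)
    as.numeric(names(tb)[which.max(tb)])
  } else NA_real_
  structure(list(t = t, stage = as.integer(s), epoch_s = epoch),
            class = "sleep_labels")
}

#' @export
print.sleep_labels <- function(x, ...) {
  cat(sprintf("<sleep_labels> %d epochs @ %g s, span %.0f s\n",
              length(x$t), x$epoch_s, max(x$t) - min(x$t)))
  invisible(x)
}

#' Total duration of each sleep stage
#'
#' Duration per stage = number of epochs labeled with that stage times the
#' epoch length.
#'
#' @param labels A `sleep_labels` object.
#' @return Named numeric vector of seconds, one element per legal stage
#'   (0 for absent stages), plus attribute `total`.
#' @export
stage_durations <- function(labels) {
  stopifnot(inherits(labels, "sleep_labels"))
  ep <- labels$epoch_s
  if (is.na(ep)) ep <- 0
  out <- vapply(.legal_stages, function(s) sum(labels$stage == s) * ep,
                numeric(1))
  names(out) <- as.character(.legal_stages)
  attr(out, "total") <- length(labels$stage) * ep
  out
}

#' Correlate HRV metric summaries with sleep-stage durations
#'
#' Spearman correlation, across subjects, of every per-subject metric
#' summary (e.g. mean SampEn, CV RMSSD) against every stage duration;
#' cells are marked significant at raw p < 0.05 (the paper-style filter).
#' An optional Benjamini-Hochberg correction is available.
#'
#' @param summaries Data frame: one row per subject, numeric summary
#'   columns, plus a `SubjectID` column (ignored for correlation).
#' @param durations Data frame: one row per subject (same order), numeric
#'   stage-duration columns.
#' @param p_adjust `"none"` (default, raw p < 0.05) or `"BH"`.
#' @return Data frame with columns metric, stage, R, p, significant;
#'   constant metric or stage columns give NA cells (logged).
#' @export
correlate_metrics_with_stages <- function(summaries, durations,
                                          p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (nrow(summaries) != nrow(durations)) {
    stop("summaries and durations must have one row per subject, aligned")
  }
  if (nrow(summaries) < 5L) stop("need >= 5 subjects for correlation")
  mcols <- names(summaries)[vapply(summaries, is.numeric, logical(1))]
  scols <- names(durations)[vapply(durations, is.numeric, logical(1))]
  rows <- list()
  for (mc in mcols) {
    for (sc in scols) {
      xv <- summaries[[mc]]; yv <- durations[[sc]]
      ok <- is.finite(xv) & is.finite(yv)
      if (sum(ok) < 5L || stats::sd(xv[ok]) == 0 ||
          stats::sd(yv[ok]) == 0) {
        .log_event("correlation cell skipped (constant/short): ",
                   mc, " vs ", sc)
        rows[[paste(mc, sc)]] <- data.frame(
          metric = mc, stage = sc, R = NA_real_, p = NA_real_,
          stringsAsFactors = FALSE)
        next
      }
      ct <- suppressWarnings(
        stats::cor.test(xv[ok], yv[ok], method = "spearman"))
      rows[[paste(mc, sc)]] <- data.frame(
        metric = mc, stage = sc, R = unname(ct$estimate),
        p = ct$p.value, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  pv <- out$p
  if (p_adjust == "BH") pv <- stats::p.adjust(pv, "BH")
  out$significant <- !is.na(pv) & pv < 0.05
  out
}

#' Convert a bpm heart-rate series to pseudo RR intervals
#'
#' Watch-style exports often carry heart rate in bpm rather than beat
#' times; `60000 / bpm` gives a pseudo-RRI in ms. True beat-to-beat timing
#' is absent from such data, so beat-level metrics must be interpreted
#' with caution (a warning is attached).
#'
#' @param bpm Numeric vector of heart rates (bpm), all > 0.
#' @return An `rri_series` of pseudo intervals.
#' @export
bpm_to_rri <- function(bpm) {
  if (any(!is.finite(bpm)) || any(bpm <= 0)) {
    stop("bpm values must be finite and > 0")
  }
  warning("pseudo-RRI from bpm: true beat-to-beat timing is absent; ",
          "beat-level metrics are approximations", call. = FALSE)
  rri_series(60000 / bpm)
}
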
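# Recurrence-plot construction and recurrence quantification analysis.

#' Build a recurrence plot
#'
#' Delay-embeds the series, computes pairwise euclidean distances and
#' thresholds at `radius_fraction * max(distance)`. The Theiler window
#' excludes the main diagonal band `|i - j| <= theiler` from all counting.
#'
#' @param rri An `rri_series` or numeric vector.
#' @param m Embedding dimension (default 3).
#' @param delay Embedding delay in beats (default 1).
#' @param radius_fraction Threshold as a fraction of the maximum pairwise
#'   distance (default 0.2).
#' @param theiler Theiler window half-width (default 1).
#' @return An object of class `recurrence_plot`: list with the binary
#'   `matrix`, `m`, `delay`, `radius`, `theiler`.
#' @export
build_recurrence_plot <- function(rri, m = 3L, delay = 1L,
                                  radius_fraction = 0.2, theiler = 1L) {
  x <- as_numeric_series(rri)
  if (length(x) <= (m - 1L) * delay + 10L) {
    stop("series too short for recurrence embedding")
  }
  emb <- delay_embed(x, m, delay)
  n <- nrow(emb)
  d2 <- matrix(0, n, n)
  for (k in seq_len(ncol(emb))) {
    d2 <- d2 + outer(emb[, k], emb[, k], "-")^2
  }
  d <- sqrt(d2)
  dmax <- max(d)
  if (dmax == 0) stop("degenerate phase space: constant series")
  rad <- radius_fraction * dmax
  structure(list(matrix = d <= rad, m = as.integer(m),
                 delay = as.integer(delay), radius = rad,
                 theiler = as.integer(theiler)),
            class = "recurrence_plot")
}

#' @export
print.recurrence_plot <- function(x, ...) {
  cat(sprintf("<recurrence_plot> %dx%d, m=%d, delay=%d, radius=%.3g\n",
              nrow(x$matrix), ncol(x$matrix), x$m, x$delay, x$radius))
  invisible(x)
}

# Lengths of maximal TRUE runs along all superdiagonals outside the
# Theiler band (upper triangle only; the matrix is symmetric).
.diag_lengths <- function(mat, theiler) {
  n <- nrow(mat)
  out <- integer(0)
  if (theiler + 1L > n - 1L) return(out)
  for (k in (theiler + 1L):(n - 1L)) {
    v <- mat[cbind(seq_len(n - k), seq_len(n - k) + k)]
    r <- rle(v)
    out <- c(out, r$lengths[r$values])
  }
  out
}

# Vertical TRUE run lengths (whole matrix, Theiler band removed).
.vert_lengths <- function(mat, theiler, value = TRUE) {
  n <- nrow(mat)
  work <- mat
  for (off in 0:theiler) {
    idx <- seq_len(n - off)
    work[cbind(idx, idx + off)] <- NA
    work[cbind(idx + off, idx)] <- NA
  }
  out <- integer(0)
  for (j in seq_len(n)) {
    col <- work[, j]
    col <- col[!is.na(col)]
    r <- rle(col)
    out <- c(out, r$lengths[r$values == value])
  }
  out
}

# Shannon entropy (nats) of a run-length distribution.
.len_entropy <- function(lens) {
  if (!length(lens)) return(NA_real_)
  p <- table(lens) / length(lens)
  -sum(p * log(p))
}

#' Recurrence quantification measures
#'
#' Computes the 13 RQA measures from a recurrence plot: RecurrenceRate,
#' Determinism and mean/max diagonal-line statistics (L, Divergence, LEn),
#' Laminarity and vertical-line statistics (TrappingTime, VMax, VEn) and
#' the white-vertical (recurrence-free gap) statistics (W, WMax, WEn),
#' plus the Determinism/RecurrenceRate ratio.
#'
#' @param plot A `recurrence_plot`.
#' @param l_min Minimum diagonal line length (default 2).
#' @param v_min Minimum vertical line length (default 2).
#' @return Named list of the 13 measures; line-dependent measures are `NA`
#'   when no line reaches the minimum length.
#' @export
compute_rqa <- function(plot, l_min = 2L, v_min = 2L) {
  mat <- plot$matrix
  th <- plot$theiler
  n <- nrow(mat)
  # points outside the Theiler band
  keep <- abs(row(mat) - col(mat)) > th
  n_points <- sum(keep)
  n_rec <- sum(mat & keep)
  rr <- n_rec / n_points

  dl <- .diag_lengths(mat, th)          # upper triangle
  dl2 <- dl[dl >= l_min]
  # counts are per upper triangle; ratios are unaffected by symmetry
  det <- if (length(dl)) sum(dl2) / sum(dl) else NA_real_
  L <- if (length(dl2)) mean(dl2) else NA_real_
  lmax <- if (length(dl)) max(dl) else NA_real_
  div <- if (!is.na(lmax) && lmax > 0) 1 / lmax else NA_real_
  len <- .len_entropy(dl2)

  vl <- .vert_lengths(mat, th, TRUE)
  vl2 <- vl[vl >= v_min]
  lam <- if (length(vl)) sum(vl2) / sum(vl) else NA_real_
  tt <- if (length(vl2)) mean(vl2) else NA_real_
  vmax <- if (length(vl2)) max(vl2) else NA_real_
  ven <- .len_entropy(vl2)

  wl <- .vert_lengths(mat, th, FALSE)
  w <- if (length(wl)) mean(wl) else NA_real_
  wmax <- if (length(wl)) max(wl) else NA_real_
  wen <- .len_entropy(wl)

  list(
    RecurrenceRate = rr,
    Determinism = det,
    DeteRecRatio = if (!is.na(det) && rr > 0) det / rr else NA_real_,
    L = L,
    Divergence = div,
    LEn = len,
    Laminarity = lam,
    TrappingTime = tt,
    VMax = vmax,
    VEn = ven,
    W = w,
    WMax = wmax,
    WEn = wen
  )
}
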
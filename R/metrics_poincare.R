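# Poincare plot geometry, heart-rate asymmetry and fragmentation indices.
# The Poincare cloud is (x, y) = (RR_n, RR_{n+1}); points above the line of
# identity (y > x, interval lengthening) are heart-rate decelerations.

#' Poincare plot geometry
#'
#' SD1/SD2 are the sample SDs of the cloud rotated onto the axes
#' perpendicular to / along the line of identity:
#' `SD1 = sd((RR_{n+1} - RR_n)/sqrt(2))`, `SD2 = sd((RR_{n+1} + RR_n)/sqrt(2))`.
#' Derived indices: `SD1SD2 = SD1/SD2`, ellipse area `S = pi SD1 SD2`,
#' Cardiac Sympathetic Index `CSI = 4 SD2 / 4 SD1`, Cardiac Vagal Index
#' `CVI = log10(4 SD1 * 4 SD2)` and `CSI_Modified = (4 SD2)^2 / (4 SD1)`.
#'
#' @param rri An `rri_series` or numeric vector (ms).
#' @return Named list SD1, SD2, SD1SD2, S, CSI, CVI, CSI_Modified.
#'   Ratio indices are `NA` when their denominator SD is 0.
#' @export
compute_poincare <- function(rri) {
  x <- as_numeric_series(rri)
  nm <- c("SD1", "SD2", "SD1SD2", "S", "CSI", "CVI", "CSI_Modified")
  if (length(x) < 3L) {
    return(stats::setNames(as.list(rep(NA_real_, length(nm))), nm))
  }
  a <- x[-length(x)]; b <- x[-1L]
  sd1 <- stats::sd((b - a) / sqrt(2))
  sd2 <- stats::sd((b + a) / sqrt(2))
  list(
    SD1 = sd1,
    SD2 = sd2,
    SD1SD2 = if (sd2 > 0) sd1 / sd2 else NA_real_,
    S = pi * sd1 * sd2,
    CSI = if (sd1 > 0) sd2 / sd1 else NA_real_,
    CVI = if (sd1 > 0 && sd2 > 0) log10(16 * sd1 * sd2) else NA_real_,
    CSI_Modified = if (sd1 > 0) (4 * sd2)^2 / (4 * sd1) else NA_real_
  )
}

#' Heart-rate asymmetry indices
#'
#' Partitions the Poincare cloud into decelerations (above the line of
#' identity, `RR_{n+1} > RR_n`) and accelerations (below). Guzik's index
#' (GI) uses perpendicular distances to the LI, the Slope Index (SI) phase
#' angles relative to the LI, the Area Index (AI) the sector areas
#' `r^2 theta / 2`, and Porta's index (PI) the count below the LI; all as
#' percentage shares of the off-LI points. The variance-partition family
#' (SD1d/SD1a, SD2d/SD2a via distances to the centroid line, SDNNd/SDNNa
#' and the contributions C1d/C1a, C2d/C2a, Cd/Ca) uses the
#' partitioned-variance construction in which points on the LI contribute
#' half to each long-term side, so `C1d + C1a = 1`, `C2d + C2a = 1` and
#' `Cd + Ca = 1` hold exactly.
#'
#' @param rri An `rri_series` or numeric vector (ms).
#' @return Named list GI, SI, AI, PI (percent), C1d, C1a, C2d, C2a, Cd,
#'   Ca (fractions), SD1d, SD1a, SD2d, SD2a, SDNNd, SDNNa (ms). GI/SI/AI/PI
#'   are `NA` when every point lies on the LI.
#' @export
compute_asymmetry <- function(rri) {
  z <- as_numeric_series(rri)
  nm <- c("GI", "SI", "AI", "PI", "C1d", "C1a", "C2d", "C2a", "Cd", "Ca",
          "SD1d", "SD1a", "SD2d", "SD2a", "SDNNd", "SDNNa")
  if (length(z) < 3L) {
    return(stats::setNames(as.list(rep(NA_real_, length(nm))), nm))
  }
  x <- z[-length(z)]; y <- z[-1L]
  N <- length(x)
  dec <- y > x; acc <- y < x; li <- y == x
  d_li <- abs(y - x) / sqrt(2)                    # distance to LI
  d_l2 <- abs((x - mean(x)) + (y - mean(y))) / sqrt(2)  # to centroid line
  theta <- abs(atan(1) - atan(y / x))             # phase angle off the LI
  r2 <- x^2 + y^2
  sector <- theta * r2 / 2

  off <- !li
  GI <- SI <- AI <- PI <- NA_real_
  if (any(off)) {
    GI <- 100 * sum(d_li[dec]) / sum(d_li[off])
    SI <- 100 * sum(theta[dec]) / sum(theta[off])
    AI <- 100 * sum(sector[dec]) / sum(sector[off])
    PI <- 100 * sum(acc) / sum(off)
  }

  # short-term variance partition (per-point squared distance to the LI)
  sd1d2 <- sum(d_li[dec]^2) / N
  sd1a2 <- sum(d_li[acc]^2) / N
  sd1t2 <- sd1d2 + sd1a2
  # long-term: LI points contribute half to each side
  sd2d2 <- (sum(d_l2[dec]^2) + 0.5 * sum(d_l2[li]^2)) / N
  sd2a2 <- (sum(d_l2[acc]^2) + 0.5 * sum(d_l2[li]^2)) / N
  sd2t2 <- sd2d2 + sd2a2
  # total
  sdnnd2 <- 0.5 * (sd1d2 + sd2d2)
  sdnna2 <- 0.5 * (sd1a2 + sd2a2)
  sdnnt2 <- sdnnd2 + sdnna2

  list(
    GI = GI, SI = SI, AI = AI, PI = PI,
    C1d = if (sd1t2 > 0) sd1d2 / sd1t2 else NA_real_,
    C1a = if (sd1t2 > 0) sd1a2 / sd1t2 else NA_real_,
    C2d = if (sd2t2 > 0) sd2d2 / sd2t2 else NA_real_,
    C2a = if (sd2t2 > 0) sd2a2 / sd2t2 else NA_real_,
    Cd = if (sdnnt2 > 0) sdnnd2 / sdnnt2 else NA_real_,
    Ca = if (sdnnt2 > 0) sdnna2 / sdnnt2 else NA_real_,
    SD1d = sqrt(sd1d2), SD1a = sqrt(sd1a2),
    SD2d = sqrt(sd2d2), SD2a = sqrt(sd2a2),
    SDNNd = sqrt(sdnnd2), SDNNa = sqrt(sdnna2)
  )
}

# Sign runs of the successive differences with zeros dropped (a zero
# difference is neither an acceleration nor a deceleration).
.sign_runs <- function(d) {
  s <- sign(d)
  s <- s[s != 0]
  if (!length(s)) return(NULL)
  rle(s)
}

#' Heart-rate fragmentation indices
#'
#' Costa-style fragmentation of the successive-difference sign sequence
#' (zeros excluded): PIP is the percentage of inflection points, IALS the
#' inverse of the mean acceleration/deceleration run length, PSS the
#' percentage of differences in runs shorter than 3, and PAS the
#' percentage of differences in alternation runs of length >= 4.
#'
#' @param rri An `rri_series` or numeric vector (ms).
#' @return Named list PIP, IALS, PSS, PAS; all `NA` when every difference
#'   is zero.
#' @export
compute_fragmentation <- function(rri) {
  x <- as_numeric_series(rri)
  nm <- c("PIP", "IALS", "PSS", "PAS")
  if (length(x) < 4L) {
    return(stats::setNames(as.list(rep(NA_real_, length(nm))), nm))
  }
  d <- diff(x)
  runs <- .sign_runs(d)
  if (is.null(runs)) {
    return(stats::setNames(as.list(rep(NA_real_, length(nm))), nm))
  }
  nd <- sum(runs$lengths)            # nonzero differences
  n_inflect <- length(runs$lengths) - 1L
  PIP <- 100 * n_inflect / nd
  IALS <- 1 / mean(runs$lengths)
  PSS <- 100 * sum(runs$lengths[runs$lengths < 3]) / nd
  # alternation runs: maximal stretches of consecutive runs of length 1
  alt <- rle(runs$lengths == 1L)
  pas_count <- sum(alt$lengths[alt$values & alt$lengths >= 4L])
  PAS <- 100 * pas_count / nd
  list(PIP = PIP, IALS = IALS, PSS = PSS, PAS = PAS)
}
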
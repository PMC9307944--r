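# Independent oracles: deliberately naive loop-based implementations used
# only to verify the package's vectorised estimators.

# Brute-force SampEn: explicit template loops, Chebyshev distance,
# self-matches excluded, both template lengths drawn from the same
# N - m*delay windows (Richman & Moorman).
oracle_sampen <- function(x, m = 2L, r_abs, delay = 1L) {
  n <- length(x)
  nt <- n - m * delay
  if (nt < 2L) return(NA_real_)
  A <- 0L; B <- 0L
  for (i in 1:(nt - 1L)) {
    for (j in (i + 1L):nt) {
      dmax_m <- 0
      for (k in 0:(m - 1L)) {
        dmax_m <- max(dmax_m, abs(x[i + k * delay] - x[j + k * delay]))
      }
      if (dmax_m <= r_abs) {
        B <- B + 1L
        dmax <- max(dmax_m, abs(x[i + m * delay] - x[j + m * delay]))
        if (dmax <= r_abs) A <- A + 1L
      }
    }
  }
  if (A == 0L || B == 0L) return(NA_real_)
  -log(A / B)
}

# Brute-force ApEn with self-matches included.
oracle_apen <- function(x, m = 2L, r_abs, delay = 1L) {
  phi <- function(mm) {
    nt <- length(x) - (mm - 1L) * delay
    logs <- numeric(nt)
    for (i in seq_len(nt)) {
      cnt <- 0L
      for (j in seq_len(nt)) {
        dmax <- 0
        for (k in 0:(mm - 1L)) {
          dmax <- max(dmax, abs(x[i + k * delay] - x[j + k * delay]))
        }
        if (dmax <= r_abs) cnt <- cnt + 1L
      }
      logs[i] <- log(cnt / nt)
    }
    mean(logs)
  }
  phi(m) - phi(m + 1L)
}

# Brute-force RQA line statistics on a binary matrix: scans every diagonal
# and vertical explicitly.
oracle_rqa <- function(mat, theiler = 1L, l_min = 2L, v_min = 2L) {
  n <- nrow(mat)
  keep <- abs(row(mat) - col(mat)) > theiler
  rr <- sum(mat[keep]) / sum(keep)

  runs_of <- function(v, val = TRUE) {
    out <- integer(0); len <- 0L
    for (e in v) {
      if (identical(e, val)) len <- len + 1L
      else { if (len > 0L) out <- c(out, len); len <- 0L }
    }
    if (len > 0L) out <- c(out, len)
    out
  }
  dl <- integer(0)
  for (k in (theiler + 1L):(n - 1L)) {
    if (k > n - 1L) break
    v <- logical(n - k)
    for (i in seq_len(n - k)) v[i] <- mat[i, i + k]
    dl <- c(dl, runs_of(v))
  }
  vl <- integer(0); wl <- integer(0)
  for (j in seq_len(n)) {
    col <- mat[, j]
    sel <- abs(seq_len(n) - j) > theiler
    col <- col[sel]
    vl <- c(vl, runs_of(col, TRUE))
    wl <- c(wl, runs_of(col, FALSE))
  }
  ent <- function(l) {
    if (!length(l)) return(NA_real_)
    p <- table(l) / length(l)
    -sum(p * log(p))
  }
  dl2 <- dl[dl >= l_min]; vl2 <- vl[vl >= v_min]
  list(
    RecurrenceRate = rr,
    Determinism = if (length(dl)) sum(dl2) / sum(dl) else NA_real_,
    DeteRecRatio = if (length(dl) && rr > 0) (sum(dl2) / sum(dl)) / rr
                   else NA_real_,
    L = if (length(dl2)) mean(dl2) else NA_real_,
    Divergence = if (length(dl)) 1 / max(dl) else NA_real_,
    LEn = ent(dl2),
    Laminarity = if (length(vl)) sum(vl2) / sum(vl) else NA_real_,
    TrappingTime = if (length(vl2)) mean(vl2) else NA_real_,
    VMax = if (length(vl2)) max(vl2) else NA_real_,
    VEn = ent(vl2),
    W = if (length(wl)) mean(wl) else NA_real_,
    WMax = if (length(wl)) max(wl) else NA_real_,
    WEn = ent(wl)
  )
}

# Loop-based average mutual information at one lag (equal-width bins),
# independent of the package's vectorised table() implementation.
oracle_ami <- function(x, lag, bins) {
  n <- length(x) - lag
  rng <- range(x)
  br <- seq(rng[1], rng[2], length.out = bins + 1)
  cut_idx <- function(v) {
    i <- findInterval(v, br, rightmost.closed = TRUE, all.inside = TRUE)
    i
  }
  a <- cut_idx(x[1:n]); b <- cut_idx(x[(lag + 1):length(x)])
  mi <- 0
  for (ia in 1:bins) {
    for (ib in 1:bins) {
      pj <- sum(a == ia & b == ib) / n
      if (pj > 0) {
        pa <- sum(a == ia) / n; pb <- sum(b == ib) / n
        mi <- mi + pj * log(pj / (pa * pb))
      }
    }
  }
  mi
}

# Binomial multiplicative cascade: canonical multifractal fixture.
binomial_cascade <- function(levels, a = 0.3) {
  x <- 1
  for (i in seq_len(levels)) x <- as.vector(rbind(x * a, x * (1 - a)))
  x
}

# Evaluate expr under a fixed seed (tests only).
.with_seed_test <- function(seed, expr) {
  set.seed(seed)
  force(expr)
}

# Shared synthetic fixtures.
make_stationary_rri <- function(seed = 1, duration = 1500,
                                sd_rri = 40, ar1 = 0.3) {
  generate_rri(synthetic_spec(mean_rri = 850, sd_rri = sd_rri,
                              duration = duration, ar1_coeff = ar1,
                              seed = seed))
}
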
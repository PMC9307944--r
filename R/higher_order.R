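# Higher-order HRV layer: summary statistics and state modelling of each
# metric's own across-segment time series.

#' Basic fluctuation statistics of a metric series
#'
#' Mean, coefficient of variation (population SD / mean), quartile
#' coefficient of dispersion `QCD = (IQR/2) / midhinge` with
#' `midhinge = (Q3 + Q1)/2` and quartiles by midpoint interpolation, and
#' the Shannon entropy of the binned series (`ceiling(sqrt(n))` equal-width
#' bins, log base 2).
#'
#' @param metric_series Numeric vector (one HRV metric across segments).
#' @param subject_id Subject identifier carried through to the output.
#' @return Named list: subject_id, mean, coeff_variation,
#'   quartile_coefficient_dispersion, metrics_entropy. CV is `NA` when the
#'   mean is 0; QCD is `NA` when the midhinge is 0 (never an error).
#' @export
compute_basic_stats <- function(metric_series, subject_id = "") {
  x <- metric_series[is.finite(metric_series)]
  if (length(x) < 2L) stop("need >= 2 finite values for higher-order stats")
  m <- mean(x)
  cv <- if (m != 0) stats::sd(x) * sqrt((length(x) - 1) / length(x)) / m
        else NA_real_
  q1 <- percentile_midpoint(x, 25)
  q3 <- percentile_midpoint(x, 75)
  midhinge <- (q3 + q1) / 2
  qcd <- if (midhinge != 0) ((q3 - q1) / 2) / midhinge else NA_real_
  list(subject_id = subject_id,
       mean = m,
       coeff_variation = cv,
       quartile_coefficient_dispersion = qcd,
       metrics_entropy = entropy_shannon_binned(x))
}

# --- 1-D Gaussian hidden Markov model (EM / Baum-Welch) -------------------

.hmm_forward_backward <- function(x, pi0, A, mu, sigma) {
  n <- length(x); k <- length(mu)
  B <- vapply(seq_len(k), function(j) {
    stats::dnorm(x, mu[j], sigma[j]) + 1e-300
  }, numeric(n))
  alpha <- matrix(0, n, k); beta <- matrix(0, n, k); cnorm <- numeric(n)
  alpha[1, ] <- pi0 * B[1, ]; cnorm[1] <- sum(alpha[1, ])
  alpha[1, ] <- alpha[1, ] / cnorm[1]
  for (t in 2:n) {
    alpha[t, ] <- (alpha[t - 1, ] %*% A) * B[t, ]
    cnorm[t] <- sum(alpha[t, ])
    alpha[t, ] <- alpha[t, ] / cnorm[t]
  }
  beta[n, ] <- 1
  for (t in (n - 1):1) {
    beta[t, ] <- A %*% (B[t + 1, ] * beta[t + 1, ])
    beta[t, ] <- beta[t, ] / sum(beta[t, ])
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  list(gamma = gamma, B = B, alpha = alpha, beta = beta,
       loglik = sum(log(cnorm)))
}

#' Fit a Gaussian hidden Markov model to a metric series
#'
#' 1-D Gaussian HMM fitted by Baum-Welch EM with quantile-based
#' initialisation perturbed by a seeded jitter; the decoded state sequence
#' is the per-sample posterior mode. State labels are arbitrary
#' (permutation-equivalent). Marked experimental: intended for long metric
#' series, disabled by default in the batch pipeline.
#'
#' @param metric_series Numeric vector.
#' @param n_states Number of hidden states (default 2).
#' @param max_iter Maximum EM iterations (default 100).
#' @param tol Log-likelihood convergence tolerance (default 1e-6).
#' @param seed Seed for the initialisation jitter (default 1).
#' @return An object of class `state_sequence`: list with `states`
#'   (integer labels 0..n_states-1), `n_states`, `means`, `variances`,
#'   `transition`, `loglik`, `converged`.
#' @export
fit_state_model <- function(metric_series, n_states = 2L, max_iter = 100L,
                            tol = 1e-6, seed = 1L) {
  x <- metric_series[is.finite(metric_series)]
  if (length(x) < 5L * n_states) {
    stop("metric series too short for a state model (need >= ",
         5L * n_states, " points)")
  }
  if (stats::sd(x) == 0) stop("degenerate state model: constant series")
  k <- as.integer(n_states)
  rs <- .seeded_rng(seed)
  # quantile init with a small jitter so ties break deterministically
  probs <- (seq_len(k) - 0.5) / k
  mu <- as.numeric(stats::quantile(x, probs))
  mu <- mu + (rs$runif(k) - 0.5) * 1e-3 * stats::sd(x)
  sigma <- rep(stats::sd(x) / k + 1e-12, k)
  A <- matrix(0.1 / max(1, k - 1), k, k); diag(A) <- 0.9
  pi0 <- rep(1 / k, k)
  ll_prev <- -Inf; converged <- FALSE
  for (it in seq_len(max_iter)) {
    fb <- .hmm_forward_backward(x, pi0, A, mu, sigma)
    g <- fb$gamma
    # xi accumulation
    n <- length(x)
    xi_sum <- matrix(0, k, k)
    for (t in seq_len(n - 1)) {
      m <- (fb$alpha[t, ] %o% (fb$B[t + 1, ] * fb$beta[t + 1, ])) * A
      xi_sum <- xi_sum + m / sum(m)
    }
    pi0 <- g[1, ]
    A <- xi_sum / pmax(rowSums(xi_sum), 1e-300)
    w <- colSums(g)
    mu <- colSums(g * x) / w
    sigma <- sqrt(colSums(g * outer(x, mu, "-")^2) / w)
    sigma <- pmax(sigma, 1e-6 * stats::sd(x))
    if (abs(fb$loglik - ll_prev) < tol * abs(ll_prev + 1e-12)) {
      converged <- TRUE
      break
    }
    ll_prev <- fb$loglik
  }
  fb <- .hmm_forward_backward(x, pi0, A, mu, sigma)
  states <- max.col(fb$gamma) - 1L
  structure(list(states = states, n_states = k, means = mu,
                 variances = sigma^2, transition = A,
                 loglik = fb$loglik, converged = converged),
            class = "state_sequence")
}

#' @export
print.state_sequence <- function(x, ...) {
  cat(sprintf("<state_sequence> %d points, %d states, loglik %.2f%s\n",
              length(x$states), x$n_states, x$loglik,
              if (!x$converged) " (not converged)" else ""))
  invisible(x)
}

#' Higher-order summary of a segment-wise metric table
#'
#' Applies [compute_basic_stats()] to every numeric metric column of a
#' per-segment HRV table; non-numeric columns (e.g. SubjectID) and
#' all-missing columns are skipped and listed in the `skipped` attribute.
#' The output is transposed relative to the input: metrics index the rows.
#'
#' @param segment_table Data frame with one row per segment.
#' @param subject_id Subject identifier.
#' @return Data frame with columns SubjectID, metric, mean,
#'   coeff_variation, quartile_coefficient_dispersion, metrics_entropy;
#'   one row per summarised metric. Attribute `skipped` lists the skipped
#'   columns and reasons.
#' @export
summarize_metric_table <- function(segment_table, subject_id = "") {
  if (nrow(segment_table) < 2L) {
    stop("higher-order summary needs >= 2 segment rows; provide a longer recording")
  }
  rows <- list(); skipped <- list()
  for (cn in names(segment_table)) {
    col <- segment_table[[cn]]
    if (!is.numeric(col)) {
      skipped[[cn]] <- "non-numeric"
      next
    }
    if (all(!is.finite(col))) {
      skipped[[cn]] <- "all missing"
      next
    }
    if (sum(is.finite(col)) < 2L) {
      skipped[[cn]] <- "fewer than 2 finite values"
      next
    }
    st <- compute_basic_stats(col, subject_id)
    rows[[cn]] <- data.frame(
      SubjectID = subject_id, metric = cn, mean = st$mean,
      coeff_variation = st$coeff_variation,
      quartile_coefficient_dispersion = st$quartile_coefficient_dispersion,
      metrics_entropy = st$metrics_entropy,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
         else data.frame()
  attr(out, "skipped") <- skipped
  out
}
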
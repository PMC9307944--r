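# Synthetic RR-interval generation: stationary/modulated RRI, sleep
# sessions with stage-dependent parameters, and beat-level artifact
# injection with ground truth. All randomness flows from a single seeded
# generator per call; the caller's RNG state is left untouched.

#' Specification for a synthetic RRI series
#'
#' @param mean_rri Mean interval (ms).
#' @param sd_rri Marginal SD of the AR(1) noise (ms).
#' @param duration Recording duration (s).
#' @param modulation List of `c(freq, amplitude)` pairs: sinusoidal
#'   interval modulations (Hz, ms) evaluated at the cumulative beat time
#'   (first-order surrogate for respiratory sinus arrhythmia and slower
#'   rhythms).
#' @param ar1_coeff Lag-1 autocorrelation of the noise in [-1, 1]
#'   (default 0.3).
#' @param sampling_rate Peak sample rate in Hz (default 1000).
#' @param seed Integer seed (required for reproducibility).
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(mean_rri = 850, sd_rri = 40, duration = 300,
                           modulation = list(), ar1_coeff = 0.3,
                           sampling_rate = 1000, seed = 1L) {
  if (mean_rri <= 0 || duration <= 0) stop("invalid spec: non-positive scale")
  amp_sum <- if (length(modulation)) {
    sum(vapply(modulation, function(m) abs(m[2]), numeric(1)))
  } else 0
  if (mean_rri - amp_sum - 4 * sd_rri <= 0) {
    stop("invalid spec: parameters imply non-positive intervals")
  }
  if (abs(ar1_coeff) >= 1) stop("invalid spec: ar1_coeff must be in (-1, 1)")
  structure(list(mean_rri = mean_rri, sd_rri = sd_rri, duration = duration,
                 modulation = modulation, ar1_coeff = ar1_coeff,
                 sampling_rate = sampling_rate, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Internal: generate one run of intervals (ms) of total duration >= dur_s.
# Beat-time modulation makes the interval sequence depend on its own
# cumulative sum, so generation is sequential.
.gen_intervals <- function(mean_rri, sd_rri, dur_s, modulation, ar1,
                           t0 = 0) {
  n_guess <- ceiling(dur_s * 1000 / mean_rri) + 10L
  iv <- numeric(0)
  t <- t0
  e_prev <- 0
  innov_sd <- if (sd_rri > 0) sd_rri * sqrt(1 - ar1^2) else 0
  repeat {
    z <- stats::rnorm(n_guess)
    for (k in seq_len(n_guess)) {
      e <- ar1 * e_prev + innov_sd * z[k]
      mod <- 0
      if (length(modulation)) {
        for (mm in modulation) mod <- mod + mm[2] * sin(2 * pi * mm[1] * t)
      }
      x <- mean_rri + e + mod
      if (x < 1) x <- 1            # hard floor; unreachable under 4-sigma spec
      iv <- c(iv, x)
      t <- t + x / 1000
      e_prev <- e
      if (t - t0 >= dur_s) return(iv)
    }
    n_guess <- max(10L, n_guess %/% 4L)
  }
}

#' Generate a synthetic RRI series with known ground truth
#'
#' Intervals are `mean + AR(1) noise + sum of sinusoidal modulations`
#' evaluated at the cumulative beat time; peaks are the cumulative sum at
#' the stated sampling rate. Reproducible under a fixed seed.
#'
#' @param spec A `synthetic_spec`.
#' @return List with `peaks` (`peak_series`), `rri` (`rri_series`) and
#'   `truth` (the spec plus the realised beat count).
#' @export
generate_rri <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  iv <- .with_seed(spec$seed,
                   .gen_intervals(spec$mean_rri, spec$sd_rri, spec$duration,
                                  spec$modulation, spec$ar1_coeff))
  peaks <- round(c(0, cumsum(iv)) * spec$sampling_rate / 1000)
  pk <- peak_series(peaks, spec$sampling_rate, "synthetic")
  list(peaks = pk,
       rri = peaks_to_rri(pk),
       truth = c(unclass(spec), list(n_beats = length(peaks))))
}

#' Default per-stage generator parameters for sleep sessions
#'
#' Stage-dependent mean RRI, noise SD and high-frequency (respiratory)
#' modulation amplitude. Deep sleep (N3) carries the lowest short-term
#' variability, REM the highest, wake an intermediate profile with faster
#' heart rate; values are typical adult magnitudes.
#'
#' @return Data frame with columns stage, mean_rri, sd_rri, hf_amplitude.
#' @export
sleep_stage_defaults <- function() {
  data.frame(
    stage = c(0L, 1L, 2L, 3L, 5L),
    mean_rri = c(850, 950, 1000, 1050, 900),
    sd_rri = c(45, 35, 30, 15, 50),
    hf_amplitude = c(10, 15, 20, 10, 8),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic sleep session with stage labels
#'
#' Concatenates stage-wise RRI generated with stage-dependent parameters
#' and emits polysomnography-style label lines "t stage" (t in seconds
#' since start) at `epoch_s` spacing, plus exact ground-truth per-stage
#' durations.
#'
#' @param schedule Data frame or list of `c(stage, duration_s)` pairs;
#'   stages in {0, 1, 2, 3, 5}.
#' @param stage_params Per-stage parameters (default
#'   [sleep_stage_defaults()]).
#' @param epoch_s Label spacing in seconds (default 30).
#' @param hf_freq Respiratory modulation frequency in Hz (default 0.25).
#' @param ar1_coeff AR(1) coefficient of the noise (default 0.3).
#' @param sampling_rate Peak sampling rate (default 1000).
#' @param seed Integer seed (required).
#' @return List with `peaks`, `rri`, `label_lines` (character vector),
#'   `stage_durations` (named seconds) and `schedule`.
#' @export
generate_sleep_session <- function(schedule,
                                   stage_params = sleep_stage_defaults(),
                                   epoch_s = 30, hf_freq = 0.25,
                                   ar1_coeff = 0.3, sampling_rate = 1000,
                                   seed = 1L) {
  if (is.data.frame(schedule)) {
    schedule <- lapply(seq_len(nrow(schedule)),
                       function(i) c(schedule$stage[i], schedule$duration[i]))
  }
  if (!length(schedule)) stop("empty sleep schedule")
  stages <- vapply(schedule, function(s) as.integer(s[1]), integer(1))
  durs <- vapply(schedule, function(s) as.numeric(s[2]), numeric(1))
  if (!all(stages %in% c(0L, 1L, 2L, 3L, 5L))) {
    stop("illegal stage code in schedule (legal: 0,1,2,3,5)")
  }
  if (any(durs <= 0)) stop("schedule durations must be > 0")

  iv <- .with_seed(seed, {
    out <- numeric(0); t0 <- 0
    for (k in seq_along(stages)) {
      p <- stage_params[stage_params$stage == stages[k], ]
      if (nrow(p) != 1L) stop("no parameters for stage ", stages[k])
      seg <- .gen_intervals(p$mean_rri, p$sd_rri, durs[k],
                            list(c(hf_freq, p$hf_amplitude)), ar1_coeff,
                            t0 = t0)
      out <- c(out, seg)
      t0 <- t0 + sum(seg) / 1000
    }
    out
  })
  peaks <- round(c(0, cumsum(iv)) * sampling_rate / 1000)
  pk <- peak_series(peaks, sampling_rate, "synthetic_sleep")

  total <- sum(durs)
  n_lab <- floor(total / epoch_s + 1e-9)
  label_t <- (seq_len(n_lab) - 1) * epoch_s
  bounds <- cumsum(durs)
  # an epoch starting exactly on a transition belongs to the new stage
  label_stage <- stages[vapply(label_t, function(t) {
    which(t < bounds - 1e-9)[1]
  }, integer(1))]
  lines <- sprintf("%s %d", format(label_t, trim = TRUE, scientific = FALSE),
                   label_stage)
  sd_true <- tapply(durs, stages, sum)
  list(peaks = pk, rri = peaks_to_rri(pk), label_lines = lines,
       stage_durations = stats::setNames(as.numeric(sd_true),
                                         names(sd_true)),
       schedule = list(stages = stages, durations = durs))
}

#' Inject beat-detection artifacts with known ground truth
#'
#' Simulates missed beats (two adjacent intervals merged into one long
#' interval) and extra beats (one interval split into two short parts at a
#' random 40-60% point). Returns the exact positions and classes for
#' corrector benchmarking.
#'
#' @param rri An `rri_series` or numeric vector (ms).
#' @param missed_rate,extra_rate Fraction of beats affected, each in
#'   [0, 0.2].
#' @param seed Integer seed (required).
#' @return List with `rri` (corrupted `rri_series`) and `truth`
#'   (data.frame: position in the corrupted series, class, original
#'   values).
#' @export
inject_artifacts <- function(rri, missed_rate = 0.02, extra_rate = 0.02,
                             seed = 1L) {
  x <- as_numeric_series(rri)
  if (missed_rate < 0 || missed_rate > 0.2 || extra_rate < 0 ||
      extra_rate > 0.2) {
    stop("artifact rates must lie in [0, 0.2]")
  }
  .with_seed(seed, {
    n <- length(x)
    n_miss <- round(missed_rate * n)
    n_extra <- round(extra_rate * n)
    # pick non-adjacent victim indices so events never overlap
    avail <- seq_len(n - 1L)
    events <- list()
    pick <- function(k) {
      chosen <- integer(0)
      while (length(chosen) < k && length(avail) > 0) {
        i <- avail[sample.int(length(avail), 1L)]
        chosen <- c(chosen, i)
        avail <<- setdiff(avail, (i - 2L):(i + 2L))
      }
      chosen
    }
    miss_idx <- pick(n_miss)
    extra_idx <- pick(n_extra)
    marks <- rep("ok", n)
    marks[miss_idx] <- "missed"
    marks[extra_idx] <- "extra"
    out <- numeric(0)
    truth <- list()
    i <- 1L
    while (i <= n) {
      if (marks[i] == "missed" && i < n) {
        out <- c(out, x[i] + x[i + 1L])
        truth[[length(truth) + 1L]] <- data.frame(
          position = length(out), class = "missed",
          original = I(list(c(x[i], x[i + 1L]))))
        i <- i + 2L
      } else if (marks[i] == "extra") {
        u <- 0.4 + 0.2 * stats::runif(1)
        out <- c(out, x[i] * u, x[i] * (1 - u))
        truth[[length(truth) + 1L]] <- data.frame(
          position = length(out) - 1L, class = "extra",
          original = I(list(x[i])))
        i <- i + 1L
      } else {
        out <- c(out, x[i])
        i <- i + 1L
      }
    }
    truth_df <- if (length(truth)) do.call(rbind, truth) else
      data.frame(position = integer(), class = character(),
                 original = I(list()))
    list(rri = rri_series(out), truth = truth_df)
  })
}
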
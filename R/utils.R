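# Small internal utilities: seeded evaluation and run logging.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library calls never disturb user simulations.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Seeded jitter source used by fit_state_model.
.seeded_rng <- function(seed) {
  list(runif = function(n) .with_seed(seed, stats::runif(n)))
}

# Run-log collector: while a collector environment is installed (by
# run_batch or a test), log lines are appended there; they are also
# emitted with message() when the hrvsuite.verbose option is TRUE.
.log_state <- new.env(parent = emptyenv())

.log_event <- function(...) {
  txt <- paste0(...)
  if (isTRUE(getOption("hrvsuite.verbose", FALSE))) message(txt)
  if (!is.null(.log_state$collector)) {
    .log_state$collector$lines <- c(.log_state$collector$lines, txt)
  }
  invisible(txt)
}

.log_collect_start <- function() {
  .log_state$collector <- new.env(parent = emptyenv())
  .log_state$collector$lines <- character(0)
  invisible(NULL)
}

.log_collect_stop <- function() {
  lines <- if (is.null(.log_state$collector)) character(0)
           else .log_state$collector$lines
  .log_state$collector <- NULL
  lines
}
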
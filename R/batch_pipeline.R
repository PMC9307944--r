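# Per-segment metric assembly, batch execution and tabular outputs.

#' Pipeline configuration
#'
#' Collects every tunable parameter of the pipeline with its default.
#' All values are echoed into the run log for audit.
#'
#' @param sampling_rate Peak sampling rate in Hz (default 1000).
#' @param window_minutes Segment window (minutes, default 5);
#'   `window_minutes = NULL` analyses the whole recording as one segment
#'   (the "divider = 1" mode).
#' @param interval_min,interval_max Artifact bounds in seconds (adult
#'   defaults 0.4 / 1.5; use 0.33 / 0.75 for the fetal profile).
#' @param bands Frequency band definition (default [default_bands()]).
#' @param psd_fs RRI interpolation rate for the PSD (Hz, default 4).
#' @param psd_nperseg Welch segment length (default 256).
#' @param m Embedding dimension for entropies (default 2).
#' @param r Tolerance fraction of segment SD (default 0.2).
#' @param delay_max Maximum lag for the optimal-delay search (default 100).
#' @param mse_scales Coarse-grain scales for multiscale entropy
#'   (default 1:10).
#' @param rqa_m,rqa_radius RQA embedding dimension (3) and radius fraction
#'   (0.2).
#' @param hfd_kmax Higuchi k_max (default 10).
#' @param dfa1_range,dfa2_range Scale ranges in beats for alpha1/alpha2
#'   (defaults 4-16 and 16-64).
#' @param q_list MFDFA moment orders (default -5..5 without 0).
#' @param segment_mode `"beat_count"` (divider formula, default) or
#'   `"time"`.
#' @param use_hmm Fit the experimental HMM state model per metric series
#'   (default FALSE).
#' @param seed Seed for the (optional) HMM initialisation.
#' @return A list of class `hrv_config`.
#' @export
hrv_config <- function(sampling_rate = 1000, window_minutes = 5,
                       interval_min = 0.4, interval_max = 1.5,
                       bands = default_bands(), psd_fs = 4,
                       psd_nperseg = 256L, m = 2L, r = 0.2,
                       delay_max = 100L, mse_scales = 1:10,
                       rqa_m = 3L, rqa_radius = 0.2, hfd_kmax = 10L,
                       dfa1_range = c(4, 16), dfa2_range = c(16, 64),
                       q_list = setdiff(-5:5, 0),
                       segment_mode = c("beat_count", "time"),
                       use_hmm = FALSE, seed = 1L) {
  structure(list(
    sampling_rate = sampling_rate, window_minutes = window_minutes,
    interval_min = interval_min, interval_max = interval_max,
    bands = bands, psd_fs = psd_fs, psd_nperseg = psd_nperseg,
    m = m, r = r, delay_max = delay_max, mse_scales = mse_scales,
    rqa_m = rqa_m, rqa_radius = rqa_radius, hfd_kmax = hfd_kmax,
    dfa1_range = dfa1_range, dfa2_range = dfa2_range, q_list = q_list,
    segment_mode = match.arg(segment_mode), use_hmm = use_hmm,
    seed = seed), class = "hrv_config")
}

# Evaluate one metric family, catching per-metric failures: a failing
# metric yields NA cells plus a log entry, never aborts the segment.
.try_family <- function(label, expr, fallback_names) {
  tryCatch(expr, error = function(e) {
    .log_event("metric family '", label, "' failed: ", conditionMessage(e))
    stats::setNames(as.list(rep(NA_real_, length(fallback_names))),
                    fallback_names)
  })
}

# All 124 registry metrics for one segment.
.compute_segment_record <- function(seg_peaks, seg_rri, config) {
  x <- seg_rri$intervals
  rec <- stats::setNames(as.list(rep(NA_real_, 124L)),
                         hrv_metric_registry())

  td <- .try_family("time", compute_time_domain(seg_rri), .registry_time)
  rec[.registry_time] <- td[.registry_time]

  fd <- .try_family("frequency", {
    psd <- estimate_psd(seg_rri, seg_peaks, fs = config$psd_fs,
                        nperseg = config$psd_nperseg)
    compute_frequency_domain(psd, config$bands)
  }, .registry_freq)
  rec[.registry_freq] <- fd[.registry_freq]

  pc <- .try_family("poincare", compute_poincare(seg_rri),
                    .registry_poincare)
  rec[.registry_poincare] <- pc[.registry_poincare]

  as_ <- .try_family("asymmetry", compute_asymmetry(seg_rri),
                     .registry_asymmetry)
  rec[.registry_asymmetry] <- as_[.registry_asymmetry]

  fr <- .try_family("fragmentation", compute_fragmentation(seg_rri),
                    .registry_fragmentation)
  rec[.registry_fragmentation] <- fr[.registry_fragmentation]

  # segment-specific optimal delay (Fraser-Swinney); downgrade to 1 when
  # the segment is too short for the requested delay_max
  od <- estimate_optimal_delay(x, config$delay_max)
  delay <- od$delay
  if (is.na(delay)) {
    .log_event("segment too short for delay_max=", config$delay_max,
               "; optimal-delay pathway downgraded to delay=1")
    delay <- 1L
    rec[["optimal_time_delay"]] <- NA_real_
  } else {
    rec[["optimal_time_delay"]] <- od$delay_s
  }

  rq <- .try_family("rqa", {
    rp <- build_recurrence_plot(seg_rri, m = config$rqa_m, delay = delay,
                                radius_fraction = config$rqa_radius)
    compute_rqa(rp)
  }, .registry_rqa)
  rec[.registry_rqa] <- rq[.registry_rqa]

  m <- config$m; r <- config$r; scales <- config$mse_scales
  ce <- .try_family("complexity", {
    list(
      ApEn = entropy_approximate(x, m, r),
      SampEn = entropy_sample(x, m, r),
      cApEn = entropy_approximate_corrected(x, m, r, delay = delay),
      FuzzEn = entropy_fuzzy(x, m, r, delay = delay),
      ShanEn = entropy_shannon_binned(x),
      SpEn = entropy_spectral(x),
      SVDEn = entropy_svd(x, m),
      PEn = entropy_permutation(x, 3L),
      WPEn = entropy_permutation(x, 3L, weighted = TRUE),
      MSPEn = entropy_permutation_ms(x, 3L, scales = 1:5),
      CREn = entropy_cumulative_residual(x),
      DiffEn = entropy_differential(x),
      FI = fisher_information(x, m),
      MSE = entropy_multiscale(x, "MSE", m, r, scales)$value,
      CMSE = entropy_multiscale(x, "CMSE", m, r, scales)$value,
      RCMSE = entropy_multiscale(x, "RCMSE", m, r, scales)$value,
      FuzzEnMSE = entropy_multiscale(x, "FuzzEnMSE", m, r, scales,
                                     delay = delay)$value,
      FuzzEnRCMSE = entropy_multiscale(x, "FuzzEnRCMSE", m, r, scales,
                                       delay = delay)$value,
      CorrDim = fractal_corrdim(x, m),
      HFD = fractal_higuchi(x, config$hfd_kmax),
      KFD = fractal_katz(x),
      PFD = fractal_petrosian(x),
      SFD = fractal_sevcik(x),
      NLD = fractal_nld(x),
      SDA = fractal_sda(x),
      PSDslope = fractal_psdslope(x),
      RR_roughness = relative_roughness(x),
      Hurst = hurst_rs(x),
      LZC = complexity_lempelziv(x)$value,
      PLZC = complexity_lempelziv(x, permutation = TRUE)$value,
      Hjorth = hjorth_complexity(x),
      optimal_time_delay = rec[["optimal_time_delay"]]
    )
  }, .registry_complexity)
  rec[.registry_complexity] <- ce[.registry_complexity]

  dfa_mf <- .try_family("dfa", {
    out <- list()
    for (side in c("alpha1", "alpha2")) {
      rg <- if (side == "alpha1") config$dfa1_range else config$dfa2_range
      sc <- dfa_scales(rg[1], rg[2])
      out[[paste0("DFA_", side)]] <- compute_dfa(x, sc)$alpha
      mf <- compute_mfdfa(x, config$q_list, sc)
      for (f in c("Width", "Peak", "Mean", "Max", "Delta", "Asymmetry",
                  "Fluctuation", "Increment")) {
        out[[paste0("MFDFA_", side, "_", f)]] <- mf[[f]]
      }
    }
    out
  }, .registry_dfa)
  rec[.registry_dfa] <- dfa_mf[.registry_dfa]

  rec
}

#' Compute all HRV metrics segment-wise
#'
#' Cleansed peaks and RRI are segmented (divider formula) and every
#' metric family is evaluated per segment; the fuzzy/cApEn pathway uses
#' the segment's own estimated optimal delay. A failure in any single
#' metric yields a missing cell plus a log entry, never an aborted
#' segment.
#'
#' @param peaks A `peak_series` (cleaned).
#' @param rri The matching `rri_series`.
#' @param subject_id Subject identifier for the output rows.
#' @param config An `hrv_config`.
#' @return Data frame: one row per segment, the 124 registry columns plus
#'   `segment duration, s` and `SubjectID`.
#' @export
compute_hrv_segmentwise <- function(peaks, rri, subject_id = "",
                                    config = hrv_config()) {
  peaks <- as_peak_series(peaks, config$sampling_rate)
  rri <- as_rri_series(rri)
  if (is.null(config$window_minutes)) {
    segs <- list(list(peaks = peaks, rri = rri))
  } else {
    ss <- segment_series(peaks, rri, config$window_minutes,
                         mode = config$segment_mode)
    segs <- ss$segments
  }
  if (!length(segs)) stop("zero segments")
  rows <- lapply(segs, function(sg) {
    rec <- .compute_segment_record(sg$peaks, sg$rri, config)
    rec[["segment duration, s"]] <- sum(sg$rri$intervals) / 1000
    rec[["SubjectID"]] <- subject_id
    as.data.frame(rec, check.names = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out
}

#' Run the batch pipeline over one or two streams
#'
#' For each configured stream (e.g. "f" fetal / "m" maternal), every input
#' file is read, trimmed, artifact-corrected, converted to RRI, analysed
#' segment-wise and summarised; per-stream metric tables, higher-order
#' tables and artifact logs are written as CSV along with a run log. With
#' two streams the file lists must pair up one-to-one (explicit error
#' otherwise).
#'
#' @param streams Named list; each element a list with `files` (character
#'   vector of peak CSV paths), and optionally `interval_min`,
#'   `interval_max` overriding the config bounds.
#' @param config An `hrv_config`.
#' @param output_dir Output directory (created if needed).
#' @param xlsx Also write XLSX (unsupported on this install; kept as an
#'   explicit flag for interface compatibility).
#' @return Invisibly, a named list of written file paths.
#' @export
run_batch <- function(streams, config = hrv_config(),
                      output_dir = ".", xlsx = FALSE) {
  if (!length(streams)) stop("no input files: empty stream configuration")
  if (is.null(names(streams)) || any(!nzchar(names(streams)))) {
    stop("streams must be a named list")
  }
  if (xlsx) {
    stop("XLSX output is unsupported on this install; use CSV (default)")
  }
  counts <- vapply(streams, function(s) length(s$files), integer(1))
  if (any(counts == 0L)) {
    stop("no input files for stream(s): ",
         paste(names(streams)[counts == 0L], collapse = ", "))
  }
  if (length(streams) > 1L && length(unique(counts)) != 1L) {
    stop("unpaired streams: file counts differ (",
         paste(sprintf("%s=%d", names(streams), counts), collapse = ", "),
         ")")
  }
  missing_files <- unlist(lapply(streams, function(s)
    s$files[!file.exists(s$files)]))
  if (length(missing_files)) {
    stop("input files not found: ", paste(missing_files, collapse = ", "))
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  .log_collect_start()
  .log_event("run config: ",
             jsonlite::toJSON(config[setdiff(names(config), "bands")],
                              auto_unbox = TRUE))
  .log_event("package version: ",
             as.character(utils::packageVersion("hrvsuite")))
  written <- list()
  for (label in names(streams)) {
    st <- streams[[label]]
    imin <- if (!is.null(st$interval_min)) st$interval_min
            else config$interval_min
    imax <- if (!is.null(st$interval_max)) st$interval_max
            else config$interval_max
    metric_tabs <- list(); higher_tabs <- list(); art_tabs <- list()
    for (fp in st$files) {
      t0 <- proc.time()[["elapsed"]]
      sid <- sub("\\.[^.]*$", "", basename(fp))
      pk <- read_peaks_csv(fp, config$sampling_rate, label)
      pk <- trim_trailing_zeros(pk)
      corr <- correct_artifacts(pk, imin, imax)
      tab <- compute_hrv_segmentwise(corr$peaks, corr$rri, sid, config)
      metric_tabs[[fp]] <- tab
      higher_tabs[[fp]] <- summarize_metric_table(tab, sid)
      art_tabs[[fp]] <- artifact_log_frame(corr$report, sid)
      .log_event(sprintf("%s: %s -> %d segments, %d corrections, %.2f s",
                         label, basename(fp), nrow(tab),
                         nrow(corr$report$corrections),
                         proc.time()[["elapsed"]] - t0))
    }
    paths <- c(
      metrics = file.path(output_dir, paste0(label, "metrics.csv")),
      higher = file.path(output_dir, paste0("higher_", label,
                                            "metrics.csv")),
      artifacts = file.path(output_dir, paste0(label,
                                               "_artifacts_log.csv")))
    write_hrv_csv(do.call(rbind, c(metric_tabs, make.row.names = FALSE)),
                  paths[["metrics"]])
    write_hrv_csv(do.call(rbind, c(higher_tabs, make.row.names = FALSE)),
                  paths[["higher"]])
    write_hrv_csv(do.call(rbind, c(art_tabs, make.row.names = FALSE)),
                  paths[["artifacts"]])
    written[[label]] <- paths
  }
  log_path <- file.path(output_dir, "run_log.txt")
  writeLines(.log_collect_stop(), log_path)
  written$run_log <- log_path
  invisible(written)
}

#' Write an HRV table as deterministic CSV
#'
#' Values are serialised at 12 significant digits so identical runs give
#' byte-identical files and read-back agrees to 12 significant digits.
#'
#' @param tab Data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_hrv_csv <- function(tab, path) {
  tab2 <- tab
  for (cn in names(tab2)) {
    if (is.numeric(tab2[[cn]])) {
      tab2[[cn]] <- ifelse(is.na(tab2[[cn]]), "",
                           formatC(tab2[[cn]], digits = 12, format = "g"))
    }
  }
  utils::write.csv(tab2, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read back an HRV metric CSV
#'
#' @param path CSV written by [write_hrv_csv()].
#' @return Data frame with original column names.
#' @export
read_hrv_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
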
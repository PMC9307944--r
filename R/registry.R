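# The metric registry: the version-locked list of the 124 per-segment
# metric columns, in output order. Adding or removing a name is a breaking
# change (guarded by a test). Quality-control columns ("segment duration,
# s") and SubjectID are appended after the registry columns.

.registry_time <- c(
  "MeanNN", "SDNN", "RMSSD", "SDSD", "CVNN", "CVSD", "MedianNN", "MadNN",
  "MCVNN", "IQRNN", "pNN50", "pNN20", "TINN", "HTI",
  "SDANN1", "SDNNI1", "SDANN2", "SDNNI2", "SDANN5", "SDNNI5",
  "Prc20NN", "Prc80NN", "MinNN", "MaxNN")

.registry_freq <- c("ULF", "VLF", "LF", "HF", "VHF", "TP", "LFHF",
                    "LFn", "HFn", "LnHF")

.registry_rqa <- c("RecurrenceRate", "Determinism", "DeteRecRatio", "L",
                   "Divergence", "LEn", "Laminarity", "TrappingTime",
                   "VMax", "VEn", "W", "WMax", "WEn")

.registry_poincare <- c("SD1", "SD2", "SD1SD2", "S", "CSI", "CVI",
                        "CSI_Modified")

.registry_fragmentation <- c("PIP", "IALS", "PSS", "PAS")

.registry_asymmetry <- c("GI", "SI", "AI", "PI", "C1d", "C1a", "SD1d",
                         "SD1a", "C2d", "C2a", "SD2d", "SD2a", "Cd", "Ca",
                         "SDNNd", "SDNNa")

.registry_complexity <- c(
  "ApEn", "SampEn", "cApEn", "FuzzEn", "ShanEn", "SpEn", "SVDEn", "PEn",
  "WPEn", "MSPEn", "CREn", "DiffEn", "FI",
  "MSE", "CMSE", "RCMSE", "FuzzEnMSE", "FuzzEnRCMSE",
  "CorrDim", "HFD", "KFD", "PFD", "SFD", "NLD", "SDA", "PSDslope",
  "RR_roughness", "Hurst", "LZC", "PLZC", "Hjorth", "optimal_time_delay")

.registry_dfa <- c(
  "DFA_alpha1",
  paste0("MFDFA_alpha1_", c("Width", "Peak", "Mean", "Max", "Delta",
                            "Asymmetry", "Fluctuation", "Increment")),
  "DFA_alpha2",
  paste0("MFDFA_alpha2_", c("Width", "Peak", "Mean", "Max", "Delta",
                            "Asymmetry", "Fluctuation", "Increment")))

#' The HRV metric registry
#'
#' The ordered, version-locked names of the 124 metric columns of a
#' per-segment HRV record: 24 time domain, 10 frequency domain, 13
#' recurrence quantification, 7 Poincare geometry, 4 fragmentation, 16
#' heart-rate asymmetry, 32 complexity and 18 DFA/MFDFA columns.
#'
#' @return Character vector of length 124.
#' @export
hrv_metric_registry <- function() {
  c(.registry_time, .registry_freq, .registry_rqa, .registry_poincare,
    .registry_fragmentation, .registry_asymmetry, .registry_complexity,
    .registry_dfa)
}
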
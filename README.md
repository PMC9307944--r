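# hrvsuite

Comprehensive, segment-wise heart rate variability (HRV) analysis in R —
from raw R-peak times to a 124-metric-per-segment table, plus a
higher-order layer that quantifies how the HRV metrics themselves
fluctuate over time.

## Who this is for

Physiologists, sleep researchers and biosignal engineers who have
beat-detection output (R-peak sample indices or RR-interval series, from
ECG, PPG or fetal-ECG extraction) and want the widest practical HRV
feature set computed reproducibly, with artifact handling that is audited
rather than silent. R-peak *detection* from raw waveforms is deliberately
out of scope: the pipeline starts at peak times.

## What it computes

For each fixed-duration segment (default 5 min, split by the divider
formula `duration / window` over the beat array):

* **Time domain** — RMSSD, SDNN, SDSD, CVNN, CVSD, median/MAD statistics,
  pNN50/pNN20, the geometric HTI and TINN (least-squares triangular fit at
  1/128 s bins), SDANN/SDNNI at 1, 2 and 5 min.
* **Frequency domain** — Welch PSD of the 4 Hz-interpolated heart-period
  signal, integrated over the Task-Force bands ULF/VLF/LF/HF/VHF, with
  TP, LF/HF, normalised LFn/HFn and ln(HF).
* **Poincaré geometry & heart-rate asymmetry** — SD1/SD2, ellipse area
  `S = pi*SD1*SD2`, CSI/CVI, Guzik/Slope/Area/Porta indices and the full
  deceleration/acceleration variance partition (SD1d/a, SD2d/a, SDNNd/a,
  C1d/a, C2d/a, Cd/a), where a deceleration is a point above the line of
  identity (`RR_{n+1} > RR_n`).
* **Fragmentation** — PIP, IALS, PSS, PAS on the sign structure of
  successive differences.
* **Recurrence quantification** — the 13 standard RQA measures from a
  thresholded phase-space recurrence plot (radius = 0.2 of the maximal
  distance, Theiler window 1).
* **Complexity** — ApEn, SampEn, corrected ApEn, fuzzy entropy, multiscale
  families (MSE/CMSE/RCMSE and fuzzy variants), spectral/SVD/permutation/
  weighted-permutation entropies, cumulative-residual and differential
  entropy, Fisher information, Lempel–Ziv (median and ordinal
  symbolisation), Hjorth complexity, and the fractal family (Higuchi,
  Katz, Petrosian, Sevcik, NLD, SDA, PSD slope, relative roughness,
  rescaled-range Hurst, correlation dimension).
* **DFA / MFDFA** — alpha1 (4–16 beats) and alpha2 (16–64 beats) plus the
  eight multifractal singularity-spectrum features for each range.
* A **segment-specific optimal embedding delay** (first local minimum of
  the average mutual information, Fraser–Swinney) drives the fuzzy-entropy
  and corrected-ApEn pathway, instead of a fixed default delay.

The exact 124 column names are version-locked in
`hrv_metric_registry()`; every row also carries `segment duration, s` and
`SubjectID`.

On top of the segment table, `summarize_metric_table()` computes the
higher-order layer — mean, coefficient of variation (population SD/mean),
quartile coefficient of dispersion `(IQR/2)/midhinge`, and binned Shannon
entropy of each metric's across-segment series — and `fit_state_model()`
offers an experimental 2-state Gaussian hidden Markov model for long
metric series.

Sleep analysis: `parse_sleep_labels()` reads
`[subject]_labeled_sleep.txt` files (`"seconds stage"`, wake = 0, N1 = 1,
N2 = 2, N3 = 3, REM = 5), `stage_durations()` accounts per-stage time and
`correlate_metrics_with_stages()` computes Spearman correlations of
per-subject metric summaries against stage durations with the raw
p < 0.05 significance mask.

Everything is testable offline: `synthetic_spec()`/`generate_rri()`
produce AR(1)-plus-sinusoid RRI with known ground truth,
`generate_sleep_session()` stage-modulated sessions with label files, and
`inject_artifacts()` missed/extra beats for corrector benchmarking.

## Worked example

```r
library(hrvsuite)

# 25 minutes of synthetic RRI with LF (0.1 Hz) and HF (0.25 Hz)
# modulation, plus 1% missed and 1% extra beats
spec <- synthetic_spec(mean_rri = 850, sd_rri = 40, duration = 25 * 60,
                       modulation = list(c(0.1, 20), c(0.25, 15)), seed = 42)
g <- generate_rri(spec)
corrupted <- inject_artifacts(g$rri, missed_rate = 0.01, extra_rate = 0.01,
                              seed = 43)
pk <- peak_series(cumsum(c(0, corrupted$rri$intervals)), 1000)

fixed <- correct_artifacts(pk, interval_min = 0.55, interval_max = 1.5)
print(fixed$report)
#> <artifact_report> 1769 input beats, 36 corrections (rule_based_single_pass)
#>    extra_merged missed_inserted
#>              18              18

tab <- compute_hrv_segmentwise(fixed$peaks, fixed$rri, "subject01",
                               hrv_config())
dim(tab)
#> [1]   5 126      # 5 segments x (124 metrics + duration + SubjectID)

round(tab[, c("MeanNN", "RMSSD", "SDNN", "LFn", "HFn", "SampEn", "FuzzEn",
              "DFA_alpha1", "optimal_time_delay")], 3)
#>    MeanNN  RMSSD   SDNN   LFn   HFn SampEn FuzzEn DFA_alpha1 optimal_time_delay
#> 1 848.138 48.657 41.576 0.322 0.511  2.140  2.082      0.728              0.848
#> 2 846.788 49.884 46.254 0.421 0.390  2.049  1.992      0.923              0.847
#> 3 849.390 50.393 44.527 0.377 0.466  2.269  2.020      0.794              0.849
#> 4 847.501 49.641 41.003 0.340 0.506  2.171  2.090      0.747              0.848
#> 5 852.697 48.732 43.319 0.363 0.395  2.215  2.019      0.888              0.853
```

Reading: the mean interval (~848 ms), beat-to-beat variability (RMSSD
~49 ms) and overall variability (SDNN ~43 ms) recover the generator's
stated world; both modulation bands carry power (LFn + HFn ≈ 0.85 of the
spectrum); sample and fuzzy entropy sit in the noisy-series range ~2;
DFA alpha1 < 1 reflects the weakly autocorrelated AR(1) noise; and the
optimal reconstruction delay of ~0.85 s equals one beat, as expected for
near-white beat-to-beat dynamics.

```r
ho <- summarize_metric_table(tab, "subject01")
head(ho[, -1], 4)
#>   metric  mean coeff_variation quartile_coefficient_dispersion metrics_entropy
#> 1 MeanNN 848.9         0.00245                         0.00111            1.37
#> 2   SDNN  43.3         0.04436                         0.03427            1.52
#> 3  RMSSD  49.5         0.01359                         0.01168            1.52
#> 4   SDSD  49.5         0.01359                         0.01168            1.52
```

The higher-order table shows each metric's temporal stability across the
five segments: the mean interval is essentially constant (CV 0.2%),
while SDNN fluctuates more (CV 4.4%).

Batch mode (`run_batch()` or the CLI) processes paired streams, writing
`<label>metrics.csv`, `higher_<label>metrics.csv`,
`<label>_artifacts_log.csv` and a run log per stream:

```sh
exec/hrvsuite run --config cfg.yaml
exec/hrvsuite simulate --out fixtures --duration 1500 --seed 3
```

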
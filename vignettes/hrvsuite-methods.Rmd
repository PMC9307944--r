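---
title: "hrvsuite: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hrvsuite: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: what each stage
assumes, which parameters matter, what the synthetic generator does and
does not emulate, and where a design was genuinely open and a choice had
to be made. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The pipeline model

The unit of analysis is a series of R-peak times (integer sample indices
at a stated sampling rate, default 1000 Hz). The pipeline assumes peak
detection has already happened; its own stages are:

1. **Trailing-zero trimming.** Fixed-length acquisition buffers pad the
   peak channel with zeros; only the trailing zero block is removed.
2. **Artifact correction** (`correct_artifacts()`), enforcing
   physiological interval bounds with three deterministic rules applied
   in one left-to-right pass (modified positions are re-examined, so the
   pass is idempotent):
   * *ectopic*: an adjacent short/long pair (one side below
     `interval_min`, the other above `interval_max`) whose sum is within
     25% of twice the local median is replaced by two equal interpolants;
   * *missed beats*: an interval above `interval_max` is split into
     `k = round(interval / local median)` equal parts;
   * *extra beats*: an interval below `interval_min` is merged with its
     neighbour.
   All three rules conserve total recording duration exactly, and every
   change is recorded (index, class, before/after ms) in an audit log.
   The named commercial correction scheme the field often cites is not
   publicly specified at the algorithm level; this rule set reproduces
   its bound-enforcement contract while staying auditable. A published
   dRR-threshold scheme would slot in behind the same interface.
   The correction runs as a single pass (no fixed-point iteration),
   matching the upstream convention of correcting once and verifying.
3. **Peaks to RRI**: `rri = diff(peaks) / sampling_rate * 1000` (ms).
4. **Segmentation** (`segment_series()`): the number of segments is the
   divider formula — total duration in seconds over the window length —
   and beats are split into that many near-equal-count contiguous chunks
   (`numpy.array_split` semantics), which is how the upstream procedure
   slices the peak array. The divider is rounded (`round()`, not floored)
   since near-equal splitting tolerates fractional dividers; a recording
   shorter than one window yields a single segment flagged
   `last_partial`. A strict time-based mode (`segment_mode = "time"`)
   cuts at exact window multiples instead but is not the default.
   `window_minutes = NULL` treats the whole recording as one segment (the
   "divider = 1" simplification used for watch-style data).
5. **Per-segment metrics** (124 columns; `hrv_metric_registry()`), then
   the **higher-order layer** summarising each metric's across-segment
   series.

### Interval bounds

Defaults follow the two physiological profiles: fetal 0.33–0.75 s
(80–180 bpm) and maternal/adult 0.4–1.5 s (40–150 bpm)
(`artifact_profiles()`). A conflicting example setting of (0.1, 0.25) s
that appears in one upstream code block is treated as a typo — it would
declare every normal adult beat an artifact — and is not used.

## 2. Conventions that the literature leaves open

* **Standard deviations** are sample SDs (ddof = 1) throughout the metric
  families. The higher-order coefficient of variation is the exception:
  it uses the population SD (ddof = 0), matching the upstream
  `np.std(x)/np.mean(x)` convention.
* **Percentiles** (Prc20NN/Prc80NN, IQRNN, quartiles of the higher-order
  layer) use midpoint interpolation. A side effect worth knowing: both
  quartiles of a two-point series equal the midhinge, so its quartile
  coefficient of dispersion is exactly 0.
* **pNN50/pNN20** are computed on successive differences (the standard
  definition), although the source table's wording says "RR intervals";
  MedianNN is the median of the intervals themselves and
  MCVNN = MadNN/MedianNN. The source table is internally inconsistent on
  these rows; the standard definitions are used and noted here rather
  than silently guessed.
* **HTI/TINN** use the conventional 1/128 s ≈ 7.8125 ms histogram bin
  width (configurable). TINN is the baseline width of the least-squares
  triangle with apex at the modal bin. Because the bin grid is fixed in
  ms, TINN is scale-equivariant only up to quantisation.
* **Frequency bands** default to the Task-Force edges ULF [0, 0.0033),
  VLF [0.0033, 0.04), LF [0.04, 0.15), HF [0.15, 0.4), VHF [0.4, 0.5) Hz;
  the upstream method names the bands but never the edges. The PSD is
  Welch (Hann window, 50% overlap, 256-sample segments) on the heart
  period signal linearly interpolated at 4 Hz — interpolation implies an
  evenly-sampled estimator. Interpolation anchors each interval at the
  beat that closes it and floors the interpolation rate at 10 Hz.
  LFn/HFn are normalised by the total power over all five bands (TP); an
  LF+HF denominator is available (`normalize = "lf_hf"`).
* **Poincaré/asymmetry**: a deceleration is a point above the line of
  identity (`RR_{n+1} > RR_n`, interval lengthening). The Guzik index
  uses perpendicular distances to the identity line, the slope index
  phase angles `|pi/4 - atan(y/x)|`, the area index sector areas
  `r^2 theta / 2`; these two constructions are named but not fully
  specified in the source table and follow the asymmetry literature.
  The variance partition gives identity-line points half weight on each
  long-term side, so C1d + C1a = C2d + C2a = Cd + Ca = 1 exactly; within
  the asymmetry record the reference SD1²/SD2² are the population
  (uncentered) forms that make those identities exact. CVI uses log base
  10 (the vagal-index convention; the source says only "logarithm").
* **Fragmentation**: zero differences are excluded from inflection and
  run accounting (neither acceleration nor deceleration); an alternation
  segment is a maximal stretch of runs of length 1, counted into PAS when
  it spans at least 4 differences.
* **RQA**: embedding m = 3, delay from the per-segment optimal delay,
  radius = 0.2 × the maximal pairwise distance (a fixed-recurrence-rate
  convention is the flagged alternative), Theiler window 1. The source
  table's TrappingTime row conflates TT with DET/RR; both are emitted
  (`TrappingTime` = mean vertical line ≥ v_min, `DeteRecRatio` = DET/RR).

## 3. Complexity family choices

* **Tolerance** r = 0.2 × segment SD, embedding m = 2 for the
  ApEn/SampEn-type entropies. Classical ApEn/SampEn/MSE columns use
  delay 1; the "extra nonlinear" pathway (FuzzEn, FuzzEnMSE, FuzzEnRCMSE,
  cApEn) uses the segment-specific optimal delay, mirroring the upstream
  split between regular and delay-optimised estimates.
* **Optimal delay** is the first local minimum of the average mutual
  information over lags 1..100 (Fraser–Swinney). AMI uses an equal-width
  decile histogram; the curve is smoothed over 3 lags before the minimum
  search to suppress binning-parity ripple, and a flatness guard returns
  delay 1 when no lag dips below the lag-1 AMI by more than the
  histogram-MI independence bias ((bins−1)²/n nats) — for i.i.d. data the
  theoretical AMI curve is flat, so the first lag is optimal. Segments
  shorter than twice the requested maximal lag yield a missing delay and
  the dependent metrics fall back to delay 1 (logged). The tabulated
  value is converted to seconds via the mean interval
  (`delay × MeanNN / 1000`), a documented choice since the estimate is
  made in beats.
* **cApEn** follows the corrected formulation: conditional terms whose
  template matches only itself are replaced by `log(1/N)`.
* **FuzzEn** centres templates by their mean and grades similarity with
  `exp(-(d/r)^2)`.
* **Multiscale entropies** coarse-grain by non-overlapping means
  (scales 1–10 by default); CMSE averages over all offsets of a scale;
  RCMSE pools match counts across offsets before the log, which is why it
  survives short series where a single offset has no matches. The
  tolerance is fixed from the original series' SD (standard for MSE).
  The single reported number is the mean over valid scales; the
  per-scale curve is retained for diagnostics.
* **Symbolisation** for the Shannon-type entropies on continuous data is
  a `ceiling(sqrt(n))`-bin equal-width histogram (log base 2): applying
  symbol entropy to raw floats would degenerate to log(n) for all-unique
  values. Permutation entropies use ordinal patterns of order 3 with
  stable tie-breaking (a constant window is one fixed pattern), weighted
  PE weights each pattern by its embedding-vector variance, and both are
  normalised to [0, 1] by log2(3!).
* **Petrosian FD** uses the sign-changes-of-differences binarisation
  (variant choice among the published A–D family); **LZC** binarises at
  the median and normalises the LZ76 parse count by `n / log2(n)`;
  **PLZC** symbolises by ordinal patterns of order 3 (alphabet 6).
* **Relative roughness** is reported literally as the lag-1/lag-0
  autocovariance ratio as the source table defines it; the `2(1 - r1)`
  convention is available behind a flag.
* **Fisher information** uses the singular-spectrum construction (squared
  increments of the normalised singular values of the embedding matrix);
  the source names the quantity without a construction.
* **DFA** is order-1, windows from both series ends, alpha1 on 4–16
  beats, alpha2 on 16–64 (configurable). A series must span 4× the
  largest requested scale or the exponent is missing.
* **MFDFA** uses q = −5..5 without 0 and the Legendre transform of
  τ(q) = q·h(q) − 1. Width/Peak/Mean/Max/Delta are standard spectrum
  features; *Fluctuation* (mean of F(s) at q = 2 across the scales) and
  *Increment* (mean |Δh(q)|) are named in the source without definitions
  and are documented interpretations here. A spectrum whose h(q) rises by
  more than 0.2 anywhere is declared non-convergent and reported missing.

### Known numerical behaviour

* Order-1 DFA at very small scales is biased upward: white noise scores
  ≈ 0.58 over scales 4–16 (the upstream engine reproduces the same
  number). The known-limit tests therefore evaluate the estimator over
  scales 16–256, where white noise gives 0.5 and integrated noise 1.5;
  the alpha1 column keeps the conventional clinical 4–16 range.
* The Katz fractal dimension is computed on the planar curve
  (sample index, value) with euclidean distances, exactly as the source
  table describes. It is 1.0 for a straight line of any slope, but it is
  *length-dependent* for stochastic curves: the textbook "≈ 1.15 for
  random walks" stems from short waveform epochs, while 4096-sample
  Gaussian random walks score ≈ 1.04 (and the popular amplitude-only
  shortcut scores ≈ 1.8). The acceptance report states the honestly
  computed value.

## 4. The higher-order layer

Each metric's across-segment series is summarised by mean, population-SD
coefficient of variation, quartile coefficient of dispersion
`(IQR/2)/midhinge`, and the binned Shannon entropy described above
(flagged experimental upstream). Non-numeric and all-missing columns are
skipped and listed. A 2-state Gaussian hidden Markov model
(`fit_state_model()`, Baum–Welch EM, seeded quantile initialisation) is
implemented but disabled by default in the batch pipeline: the upstream
work commented it out because 6–8 segments per subject are too few for
state estimation, and the same minimum (≥ 5 points per state) is
enforced here with a clear error. State labels are
permutation-equivalent; downstream statistics must not attach meaning to
label identity.

## 5. What the synthetic generator does and does not emulate

`generate_rri()` draws intervals as
`mean + AR(1) noise + sum of sinusoids evaluated at cumulative beat time`.
That captures: stationary beat-to-beat variability with tunable lag-1
correlation, respiratory sinus arrhythmia (HF) and slower (LF)
oscillations in beat time, and — via `generate_sleep_session()` —
stage-dependent mean/variability/HF-amplitude shifts with exact label
ground truth. `inject_artifacts()` merges interval pairs (missed beats)
and splits intervals at a random 40–60% point (extra beats), conserving
total duration and returning exact positions.

It does **not** emulate integral-pulse-frequency modulation (modulation
acts on interval values, not on a continuous phase accumulator — the
standard first-order surrogate), ectopic-beat morphology, non-stationary
trends within a stage, or measurement jitter of wearable PPG. A green
test therefore establishes that the estimators recover a stated
stationary world, not that they are robust to every pathology of real
recordings.

Default sleep-stage parameters (mean RRI / noise SD / HF amplitude in
ms): wake 850/45/10, N1 950/35/15, N2 1000/30/20, N3 1050/15/10,
REM 900/50/8 — typical adult magnitudes with deep sleep as the
low-variability state and REM the most variable; these defaults are the
stated world of the tests and are not tuned per test.

## 6. Output contract

The registry holds exactly 124 metric columns. The source material's
printed total is 124 while its table contains a duplicated MCVNN row and
lists DFA both bare and as alpha1/alpha2; resolving the duplicates leaves
123 distinct names, and the registry's 124th column is TP (total spectral
power over the five bands) — the quantity the LFn/HFn normalisation
already computes and the least arbitrary completion of the printed total.
Each row additionally carries `segment duration, s` (Σ intervals / 1000)
and `SubjectID`. CSV output is deterministic (12 significant digits;
byte-identical across repeat runs with the HMM off). XLSX is accepted as
an interface flag but unsupported on this installation (no xlsx writer
available); CSV is the default and the tested path.

## 7. Limitations

* The artifact corrector is rule-based; pathological series (e.g. bound
  pairs excluding any valid split) raise "uncorrectable series" rather
  than guessing.
* Spearman correlation cells for constant summaries are reported missing,
  and no multiple-testing correction is applied by default (the upstream
  analysis filters at raw p < 0.05); Benjamini–Hochberg is available
  behind a flag.
* bpm-derived pseudo-RRI (`bpm_to_rri()`) lacks true beat-to-beat timing;
  beat-level metrics computed from it are approximations, and the
  function warns accordingly.
* Cross-recurrence/joint analysis of paired streams, wavelet spectra and
  surrogate-data testing are out of scope.
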
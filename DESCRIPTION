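Package: hrvsuite
Title: Comprehensive Segment-Wise Heart Rate Variability Analysis
Version: 0.1.0
Authors@R:
    person("HRV", "Suite Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for heart rate variability (HRV) analysis from R-peak
    times or RR-interval series: trailing-zero trimming, rule-based
    artifact correction with an audit log, fixed-duration segmentation,
    and computation of a 124-metric-per-segment output spanning time
    domain, frequency domain, Poincare plot geometry, heart rate
    asymmetry and fragmentation, recurrence quantification, entropy,
    fractal-dimension and (multifractal) detrended fluctuation analysis
    families, with a segment-specific optimal embedding delay for the
    fuzzy-entropy pathway.  A higher-order layer summarises the temporal
    fluctuation of each HRV metric across segments (mean, coefficient of
    variation, quartile coefficient of dispersion, entropy, optional
    Gaussian hidden Markov state model).  Includes a synthetic RR-interval
    and sleep-session generator, batch execution over paired streams,
    sleep-stage label parsing, and Spearman correlation of metric
    summaries with sleep-stage durations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
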
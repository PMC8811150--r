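Package: cogload
Title: Cognitive-Load Analysis of Single-Channel Frontal EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for continuous cognitive-load
    monitoring with a single frontal EEG channel. Generates seeded synthetic
    cohorts of simulator-training trials (load trajectories, EEG with
    load-dependent delta/theta content, coupled behavioral scores), computes
    wavelet-packet brain-activity features with best-basis selection and
    robust pruning, derives a linear-discriminant load biomarker normalized
    to 1-100 alongside classical Welch band powers, and runs the trial-level
    statistical battery: normality/variance gating, dummy-coded linear mixed
    models with Wald inference and Westfall-style effect sizes, exact paired
    Wilcoxon tests, repeated-measures correlations, feature selection,
    session comparisons, and a priori paired-t power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    car,
    jsonlite,
    lme4,
    stats,
    utils
Suggests:
    MASS,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
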
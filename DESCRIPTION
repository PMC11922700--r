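Package: impactEEG
Title: Detecting Sub-Concussive Impact Effects in Resting EEG with
    Permutation-Calibrated Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for detecting electrophysiological
    change after sub-concussive head impacts in resting EEG. Generates seeded
    synthetic cohorts with the pre / 1 h post / 24 h post design (32-channel
    10-10 montage, four crossed eyes-by-posture conditions, configurable
    lag-specific spectral effects, an exercise confound, and stereotyped ocular
    and jump artifacts), preprocesses recordings (zero-phase band-pass, average
    reference, ICA ocular-template rejection, 15-SD sliding-window peak-to-trough
    exclusion), extracts Welch band-power features, classifies sessions with
    gradient-boosted trees under subject-grouped cross-validation and
    Tree-Parzen hyperparameter search, and calibrates significance with
    shuffled-label randomization tests, cross-lag transfer and subgroup
    analyses.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    zoo,
    xgboost,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
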
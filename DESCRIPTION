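Package: eegprog
Title: Computational EEG Markers and Machine-Learning Prognosis of Seizure Recurrence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extracting linear and non-linear computational markers
    (band power, peak alpha frequency, Hurst exponent, line length, correlation
    dimension, and approximate/sample/fuzzy/permutation/spectral entropies) from
    annotated multichannel routine EEG, evaluating seizure-recurrence classifiers
    under patient-grouped nested cross-validation with quantile aggregation of
    epoch-level predictions and influence-function (LeDell) or DeLong confidence
    intervals, and running post-hoc subgroup, per-marker, and survival analyses
    (Cox proportional hazards, Kaplan-Meier). Includes a synthetic-cohort
    generator producing annotated EDF recordings with known class-dependent
    spectral and complexity structure and censored time-to-seizure outcomes, so
    the whole pipeline can be exercised and validated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    glmnet,
    e1071,
    ranger,
    xgboost,
    survival,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
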
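Package: cadsound
Title: Acoustic Coronary Artery Disease Scoring from Diastolic Heart Sounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes an acoustic 0-100 risk score for obstructive coronary
    artery disease from single-channel phonocardiogram recordings. The pipeline
    detects heart cycles without ECG gating, extracts the quiescent
    mid-diastolic (diastasis) window between the third and fourth heart sounds,
    derives four acoustic measures (low/high frequency power ratio, principal
    component projection of the diastolic spectrum, auto-mutual information,
    and normalized fourth heart sound amplitude), and combines them with a
    Fisher linear discriminant calibrated to a 0-100 point scale. A full
    diagnostic evaluation suite is included: tie-corrected ROC/AUC with DeLong
    confidence intervals and paired tests, the Liu optimal cut-point, binary
    diagnostic metrics, categorical and continuous net reclassification indices,
    integrated discrimination improvement, repeated stratified cross-validation,
    and pre-test probability modelling in the Diamond-Forrester tradition.
    A synthetic phonocardiogram and cohort simulator with exact ground truth
    makes the whole pipeline testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    MASS,
    withr,
    yaml
Config/testthat/edition: 3
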
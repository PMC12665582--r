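Package: sleepdepEEG
Title: EEG Feature Pipeline for Detecting Acute Sleep Deprivation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for discriminating acute sleep deprivation
    from well-rested wakefulness in multi-channel resting-state EEG. Provides a
    synthetic two-session cohort simulator with per-subject spectral
    fingerprints, deterministic preprocessing (resampling, zero-phase FIR
    band-pass, common average reference, fixed-length epoching, amplitude-based
    rejection), a 2481-dimensional feature extractor (Morlet continuous wavelet
    transform band descriptors, Welch spectral measures, phase-locking value and
    coherence connectivity, weighted graph-theoretic network metrics),
    leakage-safe chi-squared plus neighbourhood-component-analysis feature
    selection, nested stratified (group) cross-validation over random forest,
    gradient boosting and support vector classifiers, confusion-matrix and ROC
    evaluation with Friedman and Dunn model comparison, and fold-aligned
    SHAP-style interpretability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    igraph,
    ranger,
    xgboost,
    e1071,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
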
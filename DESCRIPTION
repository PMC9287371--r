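Package: screenrisk
Title: Longitudinal Risk Prediction for Cervical Cancer Screening Histories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Incremental risk estimators for irregular three-state cervical
    screening histories (normal / low-grade / high-grade): a matrix
    factorization estimator built on latent state profiles, a
    graph-regularized variant, a continuous-time hidden Markov model
    forward filter, and feature-based comparators (multinomial logistic
    regression, random forest, gradient tree boosting). Includes a
    calibrated synthetic cohort simulator emulating registry screening
    data (class imbalance, irregular visit times, age drift in the state
    distribution), age-stratified adaptive probability thresholding fit
    by maximizing the multiclass Matthews correlation coefficient with
    differential evolution, stratified Brier scores, absolute risk
    curves and a relative-deviation calibration indicator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    nnet,
    ranger,
    xgboost,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
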
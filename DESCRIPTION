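Package: gwobesity
Title: Geographically Weighted Lasso and Explainable Classification of
    Obesity Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-track analysis pipeline for district-level obesity
    epidemiology. The individual track prepares survey-like records (BMI
    computation and labeling at the 25 kg/m2 cut-point, no-response
    exclusion, random oversampling inside cross-validation folds), screens
    features by iterative variance-inflation-factor pruning and ordinary
    least squares p-values, cross-validates candidate classifiers, and ranks
    per-district obesity factors by exact tree-path Shapley attribution. The
    district track fits a geographically weighted lasso from scratch:
    per-district L1-penalized weighted regressions with Euclidean-distance
    kernel weights, per-district penalty selection by leave-one-out weighted
    prediction error, and across-district coefficient summaries. A
    synthetic-data module generates both tracks with known ground truth
    (smooth spatially varying coefficient surfaces, a calibrated logistic
    individual model, injected duplicate and null features) for
    recovery-based testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    ranger,
    Rcpp,
    stats,
    utils,
    xgboost
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
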
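Package: sparseFC
Title: Sparse Network-Based Classification of Regional Time-Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discriminative modelling of two groups of subjects from regional
    brain time-series via Gaussian graphical models and sparse linear
    classifiers. Estimates per-subject functional-connectivity features
    (covariance, Pearson correlation, full inverse covariance, partial
    correlation, and graphical-LASSO sparse inverse covariance with
    BIC-guided penalty selection), trains L1-norm (squared hinge) and
    L2-norm linear support vector machines on vectorized connectivity
    edges, selects hyperparameters inside a nested
    leave-one-subject-per-group-out cross-validation that jointly optimizes
    accuracy and support stability, and assesses both the pooled accuracy
    and the per-edge classifier weights by permutation tests with
    false-discovery-rate correction. Includes a synthetic-data generator
    that plants known group differences in sparse precision matrices so the
    whole pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    RNifti
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
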
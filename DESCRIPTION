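Package: thresholdreg
Title: Threshold Regression Models: Estimation and Inference
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimation and hypothesis testing for threshold (change-point)
    generalized linear regression models with step, hinge, segmented and
    stegmented threshold effects, allowing adjustment for additional
    covariates. Provides an exact profile-likelihood grid search and a fast
    smooth-approximation search for the maximum likelihood estimate of the
    threshold, maximal score and maximal likelihood-ratio tests of the
    threshold-effect null hypothesis with Monte-Carlo-calibrated p-values,
    model-based and model-robust (bootstrap and sandwich) confidence
    intervals, and a simulation harness for bias, interquartile-range and
    type-1-error studies.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    pracma,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    sandwich
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
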
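Package: opilearn
Title: Learning Curves and Case-Complexity Models from Robotic Surgery
    Performance Indicators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates and analyses registries of robotic ventral hernia
    repairs described by objective performance indicators (OPIs).
    Provides a synthetic cohort generator with a planted skill dynamic,
    feature encoding for clinical and OPI covariate sets, an iterative
    multi-family model competition predicting three-level case complexity
    with F1-based selection and SHAP feature rankings, an OPI learning
    curve built from a joint t-SNE embedding of monthly case bins with
    gap- and volume-weighted Euclidean distances and Savitzky-Golay
    smoothing, and a Novice/Expert skill segmentation from exponential
    decay fits to eigenvalue and convex-hull dispersion traces.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    readr,
    jsonlite,
    yaml,
    signal,
    minpack.lm,
    ranger,
    xgboost,
    rpart,
    e1071,
    nnet,
    caret,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
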
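Package: fcbench
Title: Regularized Partial-Correlation Functional Connectivity and
    Simulation Benchmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimation of functional connectivity (FC) from node-by-time
    activity matrices with five estimators (pairwise Pearson correlation,
    unregularized partial correlation, graphical lasso, ridge-penalized
    partial correlation, and principal-component regression), together
    with cross-validated hyperparameter selection by held-out time-series
    prediction.  Includes a modular scale-free ground-truth network
    simulator driven by a linear structural model, plus an evaluation
    battery: test-retest reliability (between-session similarity and
    one-way random-effects ICC), ground-truth and structural similarity,
    motion-confound QC-FC screening, activity-flow mapping, and
    individual-difference prediction with nested cross-validated ridge
    regression.  Benchmark drivers reproduce the reliability/validity
    trade-off of regularized partial correlation on fully synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
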
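Package: hypoSig
Title: Hypoxia Gene Signature Derivation and Prognostic Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Derives hypoxia gene expression signatures from paired
    hypoxic/normoxic cell-line profiles by combining l1-l2 regularized
    feature selection (damped iterative soft-thresholding with a ridge
    de-biasing stage, nested leave-one-out loops and a selection-frequency
    score) with per-line fold-change and BH-corrected t-test differential
    expression, and evaluates the resulting signature as a prognostic factor
    in a tumor cohort via k-means stratification, a random-signature
    permutation stability test, and Kaplan-Meier, log-rank and multivariate
    Cox proportional-hazards analyses. Includes simulators for paired
    cell-line experiments and survival cohorts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    survival,
    glmnet,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
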
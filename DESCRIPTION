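Package: hteforest
Title: Honest Causal Forests for Heterogeneous Effects of Early-Life
    Stress in Multi-Site Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Doubly robust estimation of average and conditional treatment
    effects of a binary early-life stress exposure on continuous child
    psychopathology outcomes in multi-site cohorts. Implements an honest
    causal forest with gradient-style splitting, cluster-aware subsampling
    and seed-ensemble merging; augmented inverse-propensity weighted (AIPW)
    scores with cluster-robust inference; the best-linear-predictor
    calibration test; an iterative three-step covariate-selection procedure
    based on split-frequency variable importance; group average treatment
    effect (GATE) stratification with monotonicity checks; partial-dependence
    classification of risk and protective effect modifiers; and a synthetic
    multi-site cohort generator with a known ground-truth effect surface for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    ranger,
    sandwich,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    caret,
    optparse
Config/testthat/edition: 3
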
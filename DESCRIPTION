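Package: facescreen
Title: Simulated Face-Image Screening Studies with Nested Cross-Validation
    and Expert Benchmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for end-to-end simulation and evaluation of matched
    case-control facial-image classification studies. Generates synthetic
    cohorts with a parametric disease effect on facial geometry (wider
    face, enlarged jaw and nose, thicker lips, stronger in males),
    video-like yaw sweeps, and simulated expert raters with individual
    operating points and intrarater repeatability.  Plans pair-cohesive,
    class-stratified nested cross-validation with hyperparameter-search
    splits; trains lightweight two-phase image classifiers; derives
    Youden-index thresholds with three-view majority voting; and compares
    classifier ensembles against an expert-rater ensemble using bootstrap
    confidence intervals, Cohen's kappa intrarater reliability, agreement
    decompositions and subgroup analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    e1071,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
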
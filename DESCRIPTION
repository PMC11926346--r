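Package: reservoirMC
Title: Linear Memory Capacity of Brain Connectomes as Computational Reservoirs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Treats weighted anatomical brain networks as echo-state reservoirs
    and measures their linear memory capacity: the summed Pearson correlation
    between delayed random input signals and trained linear readouts of the
    reservoir states. Provides cohort-level network preparation (consistency
    filtering by coefficient of variation, proportional density thresholding,
    spectral normalization, node lesioning), global, regional and lesional
    memory capacity, density sweeps summarized as band areas under the curve,
    a synthetic aging-cohort generator for end-to-end testing, and the
    downstream statistical layer: permutation group tests, linear models with
    covariates, FDR-corrected regional age associations, partial least squares
    with variable-importance-in-projection scores, and a multilayer perceptron
    for age regression and young/old classification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    MASS,
    stats,
    utils,
    tools,
    yaml,
    pROC
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
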
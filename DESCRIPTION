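Package: bmigap
Title: Normative Brain-Based BMI Modeling and Gap-Score Analysis
Version: 0.1.0
Authors@R:
    person("bmigap", "authors", email = "artifacts@example.org", role = c("aut", "cre"))
Description: Predicts body-mass index from voxel-wise gray-matter-volume images
    with a leakage-free, repeated nested cross-validation pipeline (Gaussian
    smoothing, age residualization, site-offset correction, PCA, min-max
    scaling, linear nu-SVR), quantifies individualized deviations as BMIgap
    (predicted minus measured BMI, bias-corrected), derives cross-validation
    ratio and sign-based consistency reliability maps with FDR control,
    overlaps them with a disease classifier's maps, links overlap regions to
    clinical features via sparse partial least squares with permutation and
    bootstrap inference, and evaluates BMIgap as a predictor of future weight
    gain. Ships a synthetic gray-matter phantom generator so the whole
    analysis is testable without restricted clinical data, plus minimal
    NIfTI-1 input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
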
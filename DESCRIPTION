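Package: rsnpredict
Title: Resting-State Network Analysis and Single-Subject Prediction of
    Treatment Outcome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis pipeline for predicting trauma-focused
    psychotherapy outcome from resting-state fMRI networks: meta-ICA
    group-network discovery, dual regression of single-subject network
    maps, voxelwise group inference with threshold-free cluster
    enhancement (TFCE) and permutation-based family-wise error control
    pooled across networks, Gaussian process classification with nested
    cross-validated feature selection, label-permutation significance
    testing, reject-option evaluation, and a synthetic cohort generator
    so the full pipeline can be exercised and validated without patient
    data. Also reproduces a battery of demographic/clinical group
    statistics from printed summary data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
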
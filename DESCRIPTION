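Package: amypet
Title: Amyloid PET SUVR Quantification with MRI-Based Parcellation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies amyloid burden from paired T1 MRI and static amyloid
    PET volumes. Conforms volumes to an isotropic RAS grid, co-registers PET
    to MRI by rigid-body maximisation of Mattes-style mutual information,
    applies geometric-transfer-matrix (GTM) partial-volume correction with a
    Gaussian point-spread function, and computes volume-weighted standardized
    uptake value ratios (SUVR) over user-defined composite regions against a
    pons reference, with cutoff-based amyloid positivity classification.
    Includes the agreement-evaluation battery used to compare quantification
    tools (Welch t-tests, two-way intraclass correlation with confidence
    bounds, Bland-Altman limits of agreement, classification metrics) and a
    seeded digital-phantom generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    generics,
    rlang,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
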
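Package: remodelr
Title: Time-Lapse HRpQCT Bone Remodeling Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies local bone formation and resorption from longitudinal
    high-resolution peripheral quantitative computed tomography (HRpQCT) of the
    distal radius. Provides rigid pyramid (multiresolution) registration of
    calibrated density volumes, ladder-based assembly of adjacent axial image
    stacks across time points, periosteal contouring with cortical/trabecular
    and fracture/intact region masking, constrained Gaussian filtering,
    multidensity-threshold formation and resorption volume fractions,
    bone-to-soft-tissue signal-to-noise (BST-SNR) image quality metrics, a
    thresholded-difference comparator with cluster-size noise removal, and the
    study statistics: a partially overlapping-samples t test, Holm step-down
    multiple-testing correction, and PLS regression with leave-one-out Q2
    component selection and VIP-sorted variable inclusion. A synthetic
    digital-radius phantom generator with planted remodeling, rigid motion and
    acquisition noise makes the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    RNifti,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    tiff,
    mixOmics,
    optparse,
    withr
Config/testthat/edition: 3
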
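Package: ivoctseg
Title: Plaque-Subtype Segmentation for Intravascular OCT in Polar Coordinates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for segmenting atherosclerotic
    plaque subtypes (lipid pool, calcified lipid, fibrofatty, calcified
    fibrous) in polar-domain intravascular optical coherence tomography
    (IVOCT) B-scans. Provides a synthetic speckle-phantom generator with a
    heart/artery/frame hierarchy, lumen detection and lumen-justified
    flattening with exact inverse reshaping, polar-to-cartesian scan
    conversion, three-category training-mask construction (exclusion /
    background / target), a from-scratch attention U-Net with circular
    padding along the angular axis trained with a Tversky focal loss,
    artery-grouped random and subtype-stratified dataset splitting, and
    Dice plus A-line sensitivity/specificity evaluation. Manifests, splits,
    training histories and metrics are tibbles; results have broom-style
    tidy() and glance() methods and ggplot2 autoplot() displays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    withr,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    tiff,
    png,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
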
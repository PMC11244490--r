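Package: bamboostand
Title: Individual Moso-Bamboo Inventory from Combined Airborne and Terrestrial LiDAR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for individual-plant inventory of moso bamboo stands from
    airborne (ALS) and terrestrial (TLS) laser-scanning point clouds. Implements
    seven-parameter Helmert coarse registration from surveyed corner targets,
    iterative-closest-point fine alignment, progressive-TIN ground filtering with
    DEM-based height normalization, top-down region-growing (PCS) and culm-first
    comparative shortest-path (CSP) individual-plant segmentation, cylinder-fit
    diameter at breast height, and location-based detection and trait accuracy
    evaluation. A synthetic stand simulator renders labelled ALS-like and
    TLS-like clouds so every stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
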
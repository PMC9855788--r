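Package: maxentsdm
Title: Presence-Only Maximum-Entropy Species Distribution Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully scriptable pipeline for presence-only
    species distribution modelling with a maximum-entropy (Gibbs) niche
    model: spatial rarefaction of occurrence records to one point per grid
    cell, collinearity pruning of bioclimatic predictors at a correlation
    threshold, L1-regularised MaxEnt fitting with cloglog suitability
    output, ROC-AUC / TSS / kappa validation, maximum
    sensitivity-plus-specificity thresholding into binary habitat maps,
    and zonal habitat-area and suitability-category accounting across
    climate scenarios. Includes a virtual-species generator (correlated
    smoothed climate-like fields, known Gibbs suitability, presence
    sampling with per-cell duplication, scenario perturbation, zone
    rasters) so the whole pipeline runs and is testable without any
    external data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
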
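Package: plastispot
Title: Spatially Resolved Cell-State Plasticity Analysis for High-Resolution Spatial Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies cell-state plasticity from RNA-velocity transition
    graphs (net transcriptional flow times velocity magnitude, min-max scaled
    at cell and cell-type level) and projects it onto deconvolved spatial
    transcriptomics spots by proportion weighting. Includes bead-array quality
    control (off-tissue smear removal by count-and-neighbor filtering),
    truncated Gaussian kernel smoothing of spot expression, conversion of
    deconvolution abundances to proportions with dominant-type assignment,
    transmural layer-position profiling of annotated ventricular walls with
    binned cell-type profiles and percentile confidence intervals, sub-domain
    plasticity ranking and neighborhood-composition analysis of valve regions,
    and a synthetic tissue simulator (annulus and wedge geometries, radial
    composition gradients, planted immature-to-mature transition chains,
    off-tissue smears) with ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
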
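Package: sfdilayers
Title: Depth-Resolved Scattering from Multi-Frequency Spatial Frequency
    Domain Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates depth-resolved reduced scattering in layered turbid
    media from multi-frequency spatial frequency domain imaging (SFDI) data.
    Implements three closed-form depth-fluence models (standard diffusion
    approximation, delta-P1, and a modified delta-P1 with sinusoidal-source
    boundary conditions), a fluence-squared partial-volume weight for a thin
    top layer, a two-layer modeled scattering coefficient evaluated over
    overlapping spatial-frequency sub-sets, root-mean-square percentage error
    model scoring, and a synthetic layered-phantom generator that emulates a
    three-phase SFDI acquisition so the full pipeline can be exercised and
    tested without instrument data.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
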
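Package: lymphchip
Title: Biophysical Modelling and Quantification for a Lymphangiogenesis-on-Chip Device
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and quantification tools for a macrofluidic
    lymphangiogenesis-on-chip device: capillary pinning versus Poiseuille
    filling pressure for hydrogel loading, Darcy interstitial flow through a
    collagen gel and endothelial monolayer in series with transient head
    decay and Peclet-number analysis, finite-volume advection-diffusion
    simulation of growth-factor gradients across the multi-layer domain,
    mask-based cell and sprout morphometry with circular statistics,
    comparative-Ct relative expression and four-parameter logistic ELISA
    calibration, plus fully seeded synthetic-data generators with ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    EBImage,
    igraph,
    jsonlite,
    Matrix,
    minpack.lm,
    png,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
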
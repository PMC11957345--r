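Package: thgmyelin
Title: Label-Free Quantification of Myelin Swellings in Third-Harmonic
    Generation Microscopy Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying myelin swellings (blisters) in label-free
    third-harmonic generation (THG) microscopy of human white matter. Covers
    the full analysis chain: reading 8-bit BMP frame sequences and multi-page
    TIFF z-stacks with acquisition geometry, drift registration by phase
    correlation, inversion, disk median filtering and contrast-limited
    adaptive histogram equalization (CLAHE), sparse-annotation pixel
    classification into non-myelin probability maps with a multiscale
    feature bank and a random forest, hysteresis thresholding and 3D
    connected-component analysis with isosurface-based sphericity, swelling
    densities per cubic millimetre, and the accompanying statistical layer
    (t tests, one-way ANOVA, mixed repeated-measures ANOVA with
    Greenhouse-Geisser correction). A synthetic THG scene generator renders
    myelinated-axon volumes with planted swellings and voxel-level ground
    truth so that every stage is testable without original acquisitions,
    and an optics module implements the THG Gouy-phase intensity integral
    and an edge-spread-function resolution estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    jsonlite,
    yaml,
    ranger,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
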
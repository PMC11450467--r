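Package: xrfmap
Title: Quantitative Synchrotron X-Ray Fluorescence Imaging of Filamentous Cyanobacteria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for quantitative synchrotron X-ray fluorescence
    (XRF) nanoprobe imaging of filamentous, nitrogen-fixing cyanobacteria. Converts
    per-pixel fluorescence spectra into calibrated elemental areal-concentration maps
    (SNIP-style peak-stripping background, ratio-constrained exponentially modified
    Gaussian peak fitting, thin-film standard calibration), segments elemental
    clusters by one-dimensional k-means or fixed thresholding with two-method
    consensus boundaries, computes per-cluster morphometry, colocalization and
    concentration statistics, and reconstructs fluorescence nanotomography slices
    with a SIRT solver under a missing-wedge geometry. A synthetic filament-phantom
    generator with full ground truth makes every stage testable without beamline
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    rlang,
    generics,
    jsonlite,
    Matrix,
    pracma,
    stats,
    utils,
    tools,
    withr,
    rhdf5,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    png,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
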
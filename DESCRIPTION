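Package: sogseg
Title: Segmentation and Object Analysis for Genetically Labelled Volume EM
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reproducible computer-assisted segmentation of genetically
    labelled (miniSOG/DAB) structures in volume electron microscopy image
    stacks (SBEM, FIB-SEM). Implements bulk range-threshold segmentation
    with minimum-size and intensity-variance object filters, point-seeded
    3D region growing with iterative intensity-range trial series, and
    per-object morphometry (volume, intensity statistics, principal axes,
    aspect ratio, orientation). Includes a synthetic phantom generator
    with per-class ground truth for validating the procedures, 3D
    non-local means denoising, Gaussian smoothing and block binning,
    multi-page TIFF input/output with JSON metadata sidecars, and a
    command-line interface binding the stages into one pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
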
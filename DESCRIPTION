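Package: ctenhance
Title: Dual-Path Enhancement of CT Slices for Segmentation Preprocessing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Enhancement pipeline for computed-tomography slices aimed at
    preparing 8-bit inputs for segmentation models. Combines edge-preserving
    Perona-Malik anisotropic diffusion in Hounsfield units, a global path
    (min-max normalization followed by histogram equalization), a local path
    (window level/width mapping targeted at a tissue of interest), and a
    weighted blend of the two paths. Ships readers for DICOM series and
    NIfTI volumes with rescale-to-HU conversion, an eight-metric binary
    segmentation evaluation suite (IoU, Dice, accuracy, precision, recall,
    sensitivity, F1, specificity) with tidy reports, and a synthetic liver
    CT phantom generator with ground-truth masks and a dose-dependent
    noise model, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    png,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    generics,
    igraph,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
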
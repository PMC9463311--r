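Package: mboi
Title: Mask-Based Object Insertion for Surgical Instrument Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generates class-balanced, automatically annotated multi-instrument
    training images for surgical-instrument instance segmentation from a small
    collection of annotated single-instrument RGB-D images and background
    pictures. Instruments are cut out by their segmentation masks, spatially
    transformed with a randomized similarity transform, and pasted onto
    backgrounds without overlap; per-pixel depth and camera intrinsics are used
    to recover each instrument's metric length so that relative physical size is
    preserved across composed scenes. Includes COCO-style annotation input and
    output, a procedural fixture generator with analytic ground truth, and the
    matching evaluation machinery (score filtering, box and mask IoU reports,
    and normalized confusion matrices with IoU-gated matching).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    optparse,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
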
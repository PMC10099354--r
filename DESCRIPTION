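Package: maseg
Title: Ensemble Encoder-Decoder Segmentation of Retinal Microaneurysms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pixel-level detection of microaneurysms, the earliest visible
    lesion of diabetic retinopathy, in color fundus photographs. Breaks
    whole images into overlapping fixed-size patches, segments each patch
    with three encoder-decoder networks (U-Net, ResNet34-UNet, U-Net++)
    built on a compact compiled convolution engine, averages their
    probability maps as an ensemble, reconstructs the whole-image
    segmentation map by overlap-aware accumulation and thresholding, and
    evaluates results with pixel-set IoU and Dice metrics. Includes a
    seeded synthetic fundus generator with pixel-exact ground-truth masks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    withr,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    tiff,
    jpeg,
    optparse
Config/testthat/edition: 3
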
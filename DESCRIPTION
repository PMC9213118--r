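Package: msfanet
Title: Multiscale Fusion and Attention Network for Skin-Lesion Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A lightweight encoder-decoder convolutional network for
    dermoscopy (melanoma) lesion segmentation: a multiscale dilated-convolution
    fusion encoder, an asymmetric (1x3/3x1) skip-connection bridge, a
    calibrating decoder with deep-supervision auxiliary heads, concurrent
    spatial and channel squeeze-excitation (scSE) attention, a weighted
    cross-entropy loss and a two-stage plateau-halving learning-rate schedule
    on Adam. Includes a seeded synthetic dermoscopy-image generator emulating
    small, prominent and irregular-edge lesion morphologies, ISIC-style
    dataset loading with preprocessing and augmentation, Dice/IoU evaluation,
    parameter counting and a command-line front end. All network primitives
    (im2col convolution, batch normalization, reverse-mode differentiation,
    Adam) are implemented in the package with compiled kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    png,
    yaml,
    jsonlite,
    withr,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
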
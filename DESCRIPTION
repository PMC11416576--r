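Package: fundusseg
Title: Multi-Class Optic Nerve Head Segmentation for Fundus Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-class segmentation of the optic nerve head in
    color fundus photographs: a compact encoder-decoder convolutional network
    (custom U-Net) for six-class delineation of optic disc, optic cup, blood
    vessels and peripapillary atrophy alpha/beta zones, together with
    multi-scale (MSU-Net) and deeply supervised (BU-Net) variants, a
    multi-label Dice loss with analytic gradient, a disc-centered polar
    transformation and its inverse, run-length and color-legend mask codecs,
    patch-based training and overlap-averaged prediction protocols,
    segmentation metrics, and a seeded synthetic fundus phantom generator so
    every stage is testable without external data. The network engine
    (forward/backward passes and Adam optimization) is implemented with
    RcppArmadillo kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jpeg,
    png,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
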
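Package: trapnet
Title: Classification of Dividing-Yeast Microfluidic Trap Images with
    Convolutional and Capsule Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for classifying 60x60 single-channel
    sub-images of microfluidic yeast-aging traps into cell-configuration
    categories (empty trap, mother only, mother with daughter above or
    below, crowded trap). Provides a seeded synthetic trap-image
    generator, frame partitioning and manifest I/O, affine and
    photometric data augmentation, three trainable classifiers (a
    2-layer CNN, a 13-layer CNN, and a capsule network with dynamic
    routing implemented from its squash and routing equations),
    confusion-matrix and per-class metrics in both the 5-category
    computed space and the 4-category biological space, and
    validation-accuracy weighted ensembling with grid-search
    orchestration. The neural-network engine is written in R over BLAS with
    small compiled kernels for convolution patch extraction; no external
    deep-learning framework is required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
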
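Package: myoStage
Title: Staging Cardiomyocyte T-Tubule Development from Confocal Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classifies single-channel confocal microscopy images of
    cardiomyocytes with fluorescently stained sarcolemma into six classes:
    five t-tubule development stages plus a reject class for empty,
    out-of-focus, dead-cell and fragment images. Provides a synthetic image
    generator emulating stage-specific tubule morphology, class-balanced
    dataset assembly with two non-destructive augmentation techniques
    (flip/rotation, and mask-based object cut-out compositing), construction
    and CPU training of densely connected convolutional networks (dense
    blocks, transition layers with channel compression, global average
    pooling), macro-averaged multiclass evaluation, and a per-sample class
    probability graph for expert review.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    EBImage,
    ggplot2,
    rlang,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Classification, CellBiology, Software, Visualization
RoxygenNote: 7.3.3
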
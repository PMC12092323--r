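Package: rnascopeseg
Title: Segmentation and Counting of Chromogenic RNAscope Dots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and counts chromogenic (DAB) RNAscope dots in
    haematoxylin-counterstained bright-field histology patches. Provides a
    seeded synthetic-patch generator that paints subtractive yellow-to-brown
    dot masks with known coordinates onto nucleus-textured backgrounds, a
    convolutional encoder-decoder segmentation network (ConvNeXt-style
    backbone with nested U-Net++ decoder nodes built from heavily
    regularized upscaling blocks) together with a compact training engine
    (Tversky/Dice/Jaccard/cross-entropy losses, AdaDelta, phased curriculum
    with backbone freezing), watershed-based post-processing that reduces
    segmentation maps to single dot coordinates, and an F1 evaluator that
    matches predicted against ground-truth dots one-to-one within a pixel
    tolerance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    igraph,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
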
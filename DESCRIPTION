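Package: corneametrics
Title: Quantification of Corneal Nerve Degeneration and Epithelial Integrity
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Image and physiology analysis for mouse models of ocular surface
    desiccation. Flattens curved-cornea confocal z-stacks by tiled
    standard-deviation projection with per-tile plane bounds, counts contiguous
    nerve fragments in binarized images with an iterative flood fill and reports
    a coverage-normalized fragmentation index, quantifies corneal epithelial
    integrity from DAPI intensity line profiles via first-derivative transition
    statistics (transition delta, AUC, AUC per transition), and computes
    tear-wick and Cochet-Bonnet blink-threshold endpoints with normality-gated
    group comparisons. Includes synthetic-data generators (nerve swirl stacks,
    nuclear lattices, physiology cohorts) that carry planted ground truth so the
    whole pipeline is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
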
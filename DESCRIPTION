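Package: stovermorph
Title: Multi-Scale Morphometrics of Pretreated Lignocellulosic Biomass Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative image analysis of dilute-acid pretreated biomass
    across four imaging scales: watershed segmentation and size/shape
    descriptors of scanned particle fields; cell-wall thickness from the
    Euclidean boundary-distance map sampled at the medial axis of binarized
    confocal sections; a grayscale surface-roughness statistic for SEM
    micrographs (standard deviation of dynamic-range-normalized regions of
    interest); intra-cell-wall void and delamination area fractions from TEM
    sections via a reference-region threshold rule; and assembly of
    structure-versus-digestibility correlation tables.  Ground-truthed
    synthetic micrograph generators for all four modalities make every stage
    of the pipeline testable without original imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    png,
    tiff,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
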
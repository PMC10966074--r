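Package: beadwell
Title: Deconvolution of Multi-Bead Microwells into Single-Cell Barcodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computational toolkit for microwell-based single-nucleus RNA and
    ATAC assays in which each microwell may hold several barcoded beads and
    several preindexed nuclei. Implements read-structure parsing and
    whitelist barcode correction, identification of cell-containing wells by
    Jaccard-index bead merging with knee-point thresholding, preindex
    splitting of co-resident nuclei, assay-specific quality-control filters,
    species-mixing (barnyard) collision estimation, pseudobulk construction
    with a windowed relative-expression CNV estimator and an iterative
    hierarchical normal/malignant classifier, and cytoband-level CNV
    concordance across modalities. Ships seeded chip and CNV-study
    simulators with full ground truth so every stage is testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    optparse,
    S4Vectors,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
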
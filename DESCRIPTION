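Package: prism
Title: Cell-to-Cell Chromatin Accessibility Variability from Single-Cell ATAC-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies cell-to-cell variability of chromatin accessibility at
    user-defined genomic feature sets (transcription-factor binding sites, motif
    matches) from binarized single-cell ATAC-seq peak-by-cell matrices. Cells are
    represented as binary accessibility vectors, compared with angular cosine
    distances, embedded by principal coordinate analysis, and scored by their mean
    distance to the centroid. Technical biases are removed in two stages: division
    by the mean variability of GC- and accessibility-matched background peak sets,
    then by the mean bias-corrected variability of random negative-control peak
    sets, so that a final value of 1 means no more variation than background noise.
    Includes a titration benchmark that mixes original and GC-matched peak blocks
    across cells to synthesize known heterogeneity, scored by a concavity (U)
    statistic and the mean squared error around a LOESS fit, and a synthetic-data
    generator so the whole pipeline runs without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    igraph,
    withr,
    jsonlite,
    GenomicRanges,
    IRanges,
    Biostrings,
    Rsamtools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
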
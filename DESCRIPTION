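Package: exaptscan
Title: Detecting, Dating and Reconstructing Transposon Exonization Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how transposable-element (TE) fragments become
    parts of genes. exaptscan detects TE-consensus-derived fragments in genomic
    sequence with a local aligner, censuses copies under identity, coverage and
    deduplication thresholds, segments a TE-derived locus into homology blocks,
    detects terminal inverted repeats, dates insertions from Jukes-Cantor
    divergence to a majority-rule consensus, reconstructs the minimal point
    mutation path that converted a non-coding TE region into protein-coding
    sequence, and builds neighbor-joining trees with bootstrap support. A
    synthetic-genome simulator with machine-readable ground truth makes the
    whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    methods,
    stats,
    utils,
    Biostrings,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
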
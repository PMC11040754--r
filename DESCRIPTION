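Package: panploid
Title: Comparative Pangenome Analysis of Diploid and Allotetraploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative pangenome analysis between diploid
    progenitor genomes and an allotetraploid derivative, motivated by
    cotton (A2 and D5 diploids and the At/Dt subgenomes of tetraploid
    cotton). Implements non-reference sequence (NRS) extraction from
    contig alignments, coverage-based gene presence/absence calling with
    core/soft-core/shell/cloud classification and pan/core rarefaction,
    genome-specific k-mer discovery and clustering, nascent-versus-lost
    classification of post-polyploidization sequence differences,
    phylostratigraphic gene-age binning, single-copy gene fate analysis
    with transposable-element disruption tracing, and full-length LTR
    retrotransposon dynamics: terminal-repeat dating under the
    Jukes-Cantor model, 90/90 family clustering, genome-specificity
    assignment, amplification lifespans, retention/deletion rates, and
    LTR-gene spatial permutation statistics. A seeded synthetic
    four-genome simulator with planted ground truth supports testing
    every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    GenomeInfoDb,
    jsonlite,
    methods,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
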
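Package: repeatscape
Title: Repeat Landscape Profiling from Low-Coverage Whole-Genome Shotgun Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Characterizes the repetitive fraction of very large plant
    genomes from sub-1x pools of short whole-genome shotgun reads.
    Provides identity-thresholded read-to-contig coverage profiling with
    .sgr export, depth-ratio copy-number estimation, read-count abundance
    estimators for repeat elements and exact telomere-motif assays, a
    permissive greedy consensus assembler that reconstructs the most
    abundant repeat families from reads that never truly overlap,
    contig-level discovery of direct-repeat (candidate LTR) pairs, tandem
    arrays, simple repeats and long nongenic open reading frames, and an
    identity-binned repeat-divergence profiler for cross-genome
    comparison. A synthetic-genome simulator with a complete planted-repeat
    ledger supports end-to-end validation of every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
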
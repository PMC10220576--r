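Package: phasemir
Title: Conserved miRNA and isomiR Analysis for Plant Vegetative Phase Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A small-RNA sequencing analysis pipeline for studying conserved
    microRNAs during plant vegetative phase change. Collapses small-RNA reads
    into unique tags, assigns tags to conserved miRNA families and isomiR
    groups by mismatch- and overhang-tolerant comparison with reference mature
    miRNAs, calls differentially expressed isomiR groups between maturity
    states, predicts genomic hairpin precursors with minimal folding free
    energy index (MFEI) filtering, scores miRNA-target complementarity with an
    expectation penalty, and computes qPCR relative expression by the
    2^-ddCt method with two reference genes. Ships a seeded synthetic-data
    generator that builds a complete toy study (genome, reference miRNAs,
    per-library reads, transcripts, Ct tables) with a ground-truth manifest so
    every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    GenomicRanges,
    IRanges,
    limma,
    rtracklayer,
    S4Vectors,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    Rcpp,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
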
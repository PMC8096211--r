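Package: tescope
Title: Transposon Insertion Detection and De Novo Insertion-Rate Estimation
    from Paired-End Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects germline transposon (mobile-element) insertions from
    paired-end short-read alignments by classifying discordant and split
    read-pairs, aligning candidate reads to a transposon consensus library
    with a local Smith-Waterman aligner, clustering supporting reads into
    1p1/2p/singleton insertion calls, and estimating per-insertion population
    frequencies as S/(S+2R). Estimates genome-wide de novo (singleton)
    insertion rates per transposon family with a chimera correction based on
    end- versus center-mapping reads, including a fragmented-transposon mode.
    Ships a population sequencing simulator (germline and somatic insertions,
    chimeric read-pairs, truth tables and truth alignments), benchmark
    metrics (sensitivity/precision/F1, frequency error, breakpoint and
    transposon-end distance, per-family SSR and correlation), and a long-read
    insertion benchmark-curation workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    stats,
    utils,
    Biostrings,
    Rsamtools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
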
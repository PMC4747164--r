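Package: FoxoChIP
Title: Integrated ChIP-seq and RNA-seq Analysis of FOXO/DAF-16 Binding and
    Transcriptional Response
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the downstream analysis of transcription-factor
    ChIP-seq together with matched RNA-seq, built around endogenous
    DAF-16/FOXO profiling in C. elegans insulin-signalling mutants.
    Implements summit-centered normalized read-density metaprofiles
    (read shifting, fixed-width binning, per-million scaling, input
    subtraction, quantile normalization, rank transforms), closest-TSS
    promoter-window peak annotation, a beta-binomial (Baggerley-style)
    differential-expression test with activated/repressed/unchanged
    classification, binding-by-expression integration statistics
    (representation score, hypergeometric overlap, distance-stratified
    fold changes, per-class binding profiles), PSSM motif scanning
    against Markov background models with exact and Monte-Carlo match
    p-values, motif enrichment relative to random promoters, and
    strand-aware inter-motif spacing analysis. A synthetic-data module
    generates toy genomes, planted motifs, ChIP/input reads, peaks and
    expression counts with full ground truth so that every pipeline
    stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    limma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
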
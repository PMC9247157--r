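Package: triplexChIRP
Title: Consensus ChIRP Peaks, RNA:DNA Triplex Prediction and Region-Set
    Enrichment for Chromatin-Associated lncRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for mapping where and how a chromatin-associated
    long noncoding RNA binds the genome. Derives consensus peaks supported by
    replicate ChIRP-seq experiments, annotates peaks relative to transcription
    start sites against a random-region permutation null, searches for
    Hoogsteen-rule RNA:DNA triplexes (triplex-forming oligonucleotides and
    triplex target sites) with RNA secondary-structure accessibility masking,
    discovers merged RNA-side DNA-binding domains, runs genomic-region and
    promoter triplex enrichment tests, computes region-set odds-ratio
    enrichment against feature databases within restricted universes, and
    quantifies triplex/Alu co-occurrence including a tie-corrected
    Jonckheere-Terpstra trend test. Ships a seeded synthetic-data generator
    with planted ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    Rcpp,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
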
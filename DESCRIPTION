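Package: mirtestis
Title: Small RNA-Seq miRNA Profiling and Differential Expression for
    Cattleyak and Yak Testis Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale re-implementation of a testis small RNA-seq
    analysis workflow comparing cattleyak (CY) and yak (YK): read cleaning
    and collapsing to unique tags, catalog-based RNA-category annotation
    with a two-mismatch tolerance, novel miRNA discovery from genome-mapped
    unannotated tags via hairpin folding and the minimum free energy index
    (MFEI), TPM normalization with an Audic-Claverie exact test for
    differential expression, seed-anchored miRNA target-site scanning with
    score and energy thresholds, hypergeometric term enrichment with
    Bonferroni correction, and 2^-ddCt RT-qPCR quantification. A
    ground-truth synthetic data generator emulates the structure of the
    original six-library study so every stage is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
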
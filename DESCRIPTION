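Package: lncscape
Title: Tissue-Specificity, Transposable-Element Content and Co-Expression
    Profiling of Long Non-Coding RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative toolkit for characterising long non-coding RNAs
    (lncRNAs) from multi-tissue bulk RNA-seq expression matrices and genome
    annotation. Implements the tau tissue-specificity score with an
    expression floor, tissue correlation structure and complete-linkage
    clustering, transposable-element content of exon projections and
    promoters with ridge-regularized canonical correlation against tissue
    expression, positional classification of lncRNA:mRNA pairs (exonic
    antisense, divergent, convergent) with Spearman/Benjamini-Hochberg
    co-expression inference, cross-species expression-conservation
    classification of 1:1 orthologues, and per-gene aggregation of
    base-wise conservation scores. Ships seeded synthetic-data generators
    that emulate every pipeline input with known ground truth, plus a
    staged pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    ape,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
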
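Package: hetriplet
Title: Parent-Hybrid Triplet Transcriptome Analysis of Heterosis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for transcriptome analysis of heterosis in parent-hybrid
    triplet designs, as used in maize ear-length studies. Implements
    library-level QC summaries, median-of-ratios size factors, FPKM,
    replicate averaging, a two-group negative-binomial differential
    expression test, mid-parent construction and non-additive expression
    pattern classification (additive, high/low-parent dominance, over- and
    under-dominance), a permutation-based allele-specific expression caller
    with Benjamini-Hochberg FDR control, half-diallel triplet set logic with
    Venn region counts and hypergeometric enrichment, phenotype mid-parent
    heterosis with LSD letter grouping, the 2^-ddCt qPCR statistic, and an
    allele-resolved negative-binomial count simulator with planted truth
    labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    vcfR,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
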
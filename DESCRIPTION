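Package: eqtnpos
Title: Positional Analysis of cis-eQTLs Across Expression Platforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for studying where cis-acting expression
    quantitative trait nucleotides (eQTNs) fall relative to their target genes,
    and how single-probe 3' expression platforms distort that picture. Includes
    a synthetic-data generator with planted gene-level and exon-specific QTLs
    rendered through three observation models (single 3' probe, per-exon array,
    per-exon counts); preprocessing (within-population quantile normalization,
    permutation-calibrated principal-component selection, elastic-net
    residualization); median-polish summarization to gene level with
    exon-specific residuals; cis-window association mapping with tie-shared
    best-SNP assignment and permutation-based empirical FDR; a hierarchical
    multinomial positional model of eQTN location with annotation odds ratios
    compared by AIC; and cross-platform replication analysis of eQTN categories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Rcpp,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr,
    jsonlite
Config/testthat/edition: 3
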
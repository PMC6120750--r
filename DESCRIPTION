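Package: olfcerna
Title: Multi-Omics ceRNA Network Inference for Ossification of the
    Ligamentum Flavum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integration pipeline for a two-group (ossified vs normal
    ligamentum flavum) multi-omics transcriptome study: differential
    expression of mRNA, lncRNA, circRNA and miRNA profiles with fold-change,
    p-value and Benjamini-Hochberg FDR filtering; positional
    subclassification of lncRNAs; coding/non-coding (CNC) co-expression
    networks at a Pearson correlation threshold; negatively-correlated
    miRNA target networks backed by canonical seed-site evidence;
    circRNA-miRNA-mRNA competing-endogenous-RNA (ceRNA) triplet inference
    from shared miRNA response elements, including sites spanning the
    backsplice junction of circular transcripts; and hypergeometric
    gene-set enrichment with the -log10(p) enrichment-score convention.
    Ships a seeded synthetic-data generator that plants known differential
    expression, co-expression, binding sites and ceRNA triplets so every
    stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    limma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
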
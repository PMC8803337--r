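Package: orthosig
Title: Cross-Species Differential-Expression Signature Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing transcriptome signatures across species and
    diseases from differential-expression result tables: up/down signature
    extraction under an FDR and fold-change rule, ortholog-paired fold-change
    vectors, Spearman correlation ranking of many comparisons, a cumulative
    overlap (GSEA-like) curve with an area-versus-diagonal statistic and
    Wilcoxon rank-sum null, observed/expected hypergeometric gene-set
    enrichment with Benjamini-Hochberg adjustment, directional transcription
    factor target enrichment, and projection of bulk signatures onto
    single-cell marker sets. Includes a synthetic-data generator that plants
    shared transcriptional programs in paired two-species studies so every
    statistic can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
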
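Package: tortgwas
Title: Retinal Vessel Tortuosity Phenotyping and Genetic Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for an end-to-end genetic study of retinal vessel
    tortuosity. Computes tortuosity phenotypes (distance factor and six
    curvature-integral measures) from vessel centerlines, calls vessel type
    from pixel-wise artery/vein labels, applies image quality control and
    median/eye/timepoint aggregation, runs covariate-adjusted per-SNP linear
    association with inflation diagnostics and LD-score-regression
    heritability, aggregates SNPs into gene scores via an LD-aware weighted
    sum of chi-squared statistics evaluated in quadruple-precision
    arithmetic (tail probabilities far below 1e-100), performs rank-based
    gene-set and tissue-expression enrichment with gene fusion, LD pruning,
    inverse-variance meta-analysis and Benjamini-Hochberg replication,
    disease-variant overlap with LD proxies, and bidirectional
    inverse-variance-weighted Mendelian randomization. A synthetic-data
    module generates every input with known ground truth so the whole chain
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
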
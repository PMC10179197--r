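Package: tagshares
Title: Within-Complex Expression Shares and Sample-Ranked Enrichment for
    Translation Machinery Composition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyses the tissue-specific composition of the human translation
    machinery from gene-by-sample abundance matrices. Computes each member
    gene's share of the total expression of its protein complex or functional
    group, applies the half-mean sample-exclusion rule, tests tissue groups
    for enrichment along the share-ranked sample list with a weighted
    Kolmogorov-Smirnov running-sum statistic, a permutation null, normalized
    enrichment scores and Benjamini-Hochberg FDR, and correlates weighted
    total expression of gene sets with a ribosomal-protein reference across
    tissues. Bundles the translation-associated gene catalog, readers for
    GCT/TSV expression data, transcript- and probe-level aggregation, and a
    synthetic GTEx-like data generator with planted effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
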
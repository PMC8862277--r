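Package: dcornet
Title: Distance-Correlation-Based Gene Co-Expression Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Weighted gene co-expression network analysis built on the
    empirical distance correlation of energy statistics, with Pearson,
    Spearman and a simplified maximal information coefficient (MIC) as
    comparator metrics. Provides permutation tests of independence with
    power/ROC-curve summaries, expression-matrix filtering and normality
    screening, soft-threshold selection by scale-free-topology fit,
    topological overlap and dendrogram-based module detection, split-half
    stability and Fisher-exact module-preservation statistics, and seeded
    synthetic-data generators (gene-pair relationship families, outlier
    contamination, planted co-expression modules) so the whole pipeline is
    testable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    jsonlite
Config/testthat/edition: 3
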
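Package: appendhom
Title: Cross-Species Expression Homology Assessment for Ruminant Cranial Appendages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for assessing homology of gene expression programs
    across species with a phylogenetic outgroup, motivated by the question of
    whether bovid horns and cervid antlers share a common developmental
    origin. Provides within-species differential expression of test tissues
    against pooled somatic controls (negative-binomial quasi-likelihood
    models via edgeR), TMM normalization and grouped log-CPM summaries with a
    zero-count sentinel, the tau tissue-specificity index with strict and
    relaxed specific-gene lists, competitive gene-set ranking that accounts
    for inter-gene correlation, regulator-target overlap testing,
    self-organizing-map clustering of expression profiles with k-medoid
    grouping and gap-statistic model selection, and outgroup-conditioned
    homology calls with shared-proportion summaries. Includes a
    negative-binomial synthetic-data generator with planted gene classes so
    every stage can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    edgeR,
    limma,
    cluster,
    stats,
    utils,
    methods,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
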
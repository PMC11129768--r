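Package: rankgsea
Title: Rank-Based Single-Cell Gene-Set Scoring with Robust Rank Aggregation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores single cells against gene-set collections with six
    enrichment methods that depend only on within-cell expression ranks
    (AUCell-, UCell-, singscore-, ssGSEA-, JASMINE- and Viper-style scores),
    tests per-cluster differential enrichment with the Wilcoxon rank-sum
    test under Bonferroni correction, and aggregates the per-method results
    into one significance call per gene set and cluster with robust rank
    aggregation (RRA) order-statistic p-values. Includes readers and writers
    for MatrixMarket/CSV expression matrices, GMT gene-set collections and
    cluster label tables, a negative-binomial synthetic-data generator with
    planted enriched sets, Kendall concordance reports, plot-data tables
    with basic renderings, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
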
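Package: TraitNet
Title: Pairwise Association Networks of Binary Phenotypic Traits Across
    Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects positive and negative pairwise associations among
    binary phenotypic traits (and between traits and isolation
    environments) across species using fixed-margin checkerboard-swap
    permutation null models, and attributes those associations to
    phylogeny, intrinsic biological properties, and environment.
    Includes probabilistic imputation of missing trait scores, the
    Fritz-Purvis D statistic of phylogenetic signal for binary traits
    with random and threshold-Brownian nulls, Ward clustering of
    association profiles with bootstrap support, three-set variance
    partitioning with Ezekiel-adjusted R-squared, greedy-modularity
    community detection on signed trait networks with Fisher enrichment
    tests, gene-presence/growth association tests, and a synthetic-data
    generator that emulates the statistical structure of taxonomic
    trait compendia.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    ape,
    igraph
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    picante,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
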
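Package: isopop
Title: Population Structure, Differentiation and Trait Comparison for
    Isolated Plant Populations
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical toolkit for comparative studies of isolated plant
    populations scored with dominant molecular markers (AFLP-style binary
    band data).  Provides within-population diversity statistics
    (percentage of polymorphic loci, Nei's gene diversity, Shannon's
    information index), hierarchical analysis of molecular variance
    (AMOVA) with Phi statistics and permutation tests, pairwise
    population differentiation matrices, Mantel tests of isolation by
    distance, Bayesian robust two-group comparisons of population traits
    with highest-density-interval decision rules, a hierarchical two-way
    beta-logistic model of dish-level germination counts, Spearman
    correlation screens, and an island-model simulator that generates
    every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    coda,
    geosphere,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    rjags,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
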
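Package: dietnet
Title: Individual-Based Diet Network Analysis for Predator Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Network-based analysis of individual diet specialization in
    predator populations sampled as individual-by-prey-taxon count matrices.
    Implements the E index of inter-individual diet variation built on pairwise
    proportional similarity, the relative weighted clustering index C_ws with
    extraction of dietary clusters from pairwise-significance graphs, the NODF
    nestedness metric with a cell-probability (CE) null model, and the
    Stone-Roberts C-score of checkerboard co-occurrence with a fixed-margin
    sequential-swap null. Each index carries a seeded Monte-Carlo null model
    and significance verdict. Also provides the classical covariate tests used
    alongside these indices (availability correlation, mass-niche-breadth
    regression, cluster ANOVA with Tukey HSD, Levene variance homogeneity,
    paired seasonal-shift and co-occurrence mass-difference t-tests,
    inter-nest distance comparison), readers/writers for delimited diet
    matrices and Pajek graph files, and a synthetic diet-matrix generator with
    tunable nested, clustered and checkerboard structure for power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    car,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
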
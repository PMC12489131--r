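Package: fuzzyprofiles
Title: Fuzzy Cognitive-Behavioral Profiling of Pediatric Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts overlapping ("fuzzy") cognitive and behavioral profiles
    from standardized factor scores using fuzzy C-means clustering with
    Mahalanobis membership functions, selects the number of profiles by
    silhouette, and predicts memberships for new cohorts from stored
    centroids. Includes cross-cohort harmonization, covariate
    residualization, K-nearest-neighbor imputation, split-half exploratory
    factor analysis for latent cognitive factors, a subject-centroid
    membership graph with an average-shortest-weighted-path permutation test
    for diagnosis aggregation, longitudinal profile transition and
    movement-ratio summaries, partial least squares regression of
    environmental predictors on memberships with permutation inference and
    Benjamini-Hochberg correction, and a seeded multi-cohort synthetic data
    generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    clue,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    MASS,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
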
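Package: cortsub
Title: Cortical Thickness Subtyping and Mechanisms of Longitudinal Thinning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-driven subtyping of regional cortical thickness with
    non-negative matrix factorization (NMF) consensus clustering, longitudinal
    characterization of the discovered subtypes with random-intercept mixed
    models, quantification of subtype stability over time with Krippendorff's
    alpha, and mechanism testing for subtype-specific cortical thinning:
    coordinated deformation models evaluated against geometry-preserving
    rewired network nulls and spatial-autocorrelation-preserving
    variogram-matched surrogate maps, and imaging-transcriptomics spatial
    correlation with hypergeometric over-representation analysis. Includes a
    synthetic-cohort generator (parcellations, connectomes, longitudinal
    thickness tables with planted subtypes, spatially autocorrelated gene
    expression) so the full pipeline can be exercised and validated without
    access-restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    lme4,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    emmeans,
    fgsea,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
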
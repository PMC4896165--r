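Package: catdep
Title: Exploring Dependence Between Categorical Variables via Profile
    Clustering and Informed Log-Linear Model Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage Bayesian exploration of dependence structures among
    categorical variables. A Dirichlet-process mixture of product multinomials
    with cluster-specific variable-selection switches partitions subjects by
    their covariate profiles and flags the covariates that drive the
    partitioning. The selection output is condensed into an edge-evidence
    matrix for pairs of covariates, which screens marginally independent
    covariates out of sparse contingency tables and supplies informed edge
    proposals for a reversible-jump search over graphical log-linear models.
    Includes simulation generators for mixtures of log-linear models, Poisson
    likelihood and unit-information prior machinery, Laplace enumeration for
    small model spaces, and broom-style tidiers with ggplot2 plotting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    cluster,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
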
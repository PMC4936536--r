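Package: multiscaleCAR
Title: Bayesian Multiscale Disease Mapping with Shared Spatial Random Effects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits two-level Bayesian multiscale convolution models for areal
    count-of-cases data on nested geographies (for example counties nested in
    public-health districts). Supports an independent multiscale model in
    which each scale level gets its own intrinsic CAR (ICAR) and exchangeable
    random effects, and a shared multiscale model in which the coarse-level
    spatially structured effect also enters every nested fine-level unit,
    recovering information lost when outcomes are aggregated upward.
    Inference is by Metropolis-within-Gibbs MCMC with adaptive proposals,
    Gelman-Rubin diagnostics, per-level DIC/pD and posterior-predictive MSPE
    model assessment, odds-ratio back-transformation of standardized
    covariate effects, and a synthetic-data generator for nested lattice and
    irregular geographies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
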
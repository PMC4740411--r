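Package: lerouxmap
Title: Bayesian Disease Mapping with Leroux Conditional Autoregressive Models
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Small-area disease-mapping toolkit built around indirect
    age-sex standardization and a hierarchical Bayesian Poisson model with
    Leroux conditional autoregressive (CAR) spatial random effects, fit by
    an adaptive Metropolis-within-Gibbs sampler. Computes expected counts
    and standardized mortality ratios (SMR) from stratified count tables,
    spatially smoothed SMRs, covariate-adjusted relative risks with 95%
    credible intervals, Moran's I permutation tests for spatial
    autocorrelation, variance-inflation-factor screening of collinear
    covariates, and Geweke convergence diagnostics. Includes a generative
    simulator for stratified areal count data on lattice or irregular
    contiguity graphs so every pipeline stage can be validated against
    known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
biocViews: Spatial, Bayesian, Epidemiology, Regression, Software
RoxygenNote: 7.3.3
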
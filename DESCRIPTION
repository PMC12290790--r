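Package: petpool
Title: Hierarchical Multivariate Modelling of Dynamic PET Time-Activity Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Compartmental kinetic modelling and hierarchical multivariate
    Bayesian analysis of dynamic PET time-activity curves. Provides analytic
    two-tissue compartment (2TCM) and simplified reference tissue (SRTM)
    forward models, weighted nonlinear least-squares quantification in three
    binding-potential parameterizations (BPND, BPP, BPF), a simultaneous
    hierarchical multivariate model that fits all curves of a study at once
    with partial pooling across subjects and regions, a multivariate
    hierarchical analysis of pre-estimated kinetic parameters, group-contrast
    and power-analysis utilities, and a seeded generator of synthetic
    multi-group PET cohorts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    lme4,
    mgcv,
    jsonlite,
    yaml,
    tibble,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse,
    ggplot2
Config/testthat/edition: 3
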
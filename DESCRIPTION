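Package: telotraj
Title: Longitudinal Telomere Trajectories with Random Regression Animal Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Pipeline for longitudinal relative leukocyte telomere length
    (RLTL) analysis: conversion of qPCR quantification cycles to
    calibrator-normalised RLTL with quality-control filtering, pedigree
    relationship-matrix algebra with inbreeding, restricted maximum
    likelihood (average-information REML) estimation of Legendre-polynomial
    random regression animal models, age trajectories of additive genetic
    variance, heritability and genetic correlation with delta-method
    standard errors, shape-based clustering of individual telomere profiles
    under the discrete Frechet distance, and Cox proportional-hazards
    association of profile clusters with right-censored productive
    lifespan. Includes a fully deterministic synthetic-data generator
    (pedigree, breeding-value gene dropping, qPCR plates, survival times)
    so every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    survival,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
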
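Package: twingrowth
Title: Twin-Based Latent Growth Modelling of Polygenic Effects on Height
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Piecewise-linear latent growth models for longitudinal twin
    cohorts, with ACE (additive genetic, shared and nonshared environment)
    decomposition of the growth intercept and slope fitted by
    full-information maximum likelihood. Includes construction and quality
    control of weighted polygenic scores from genotype dosages
    (Hardy-Weinberg exact test, Mendelian-consistency screens, allele
    alignment), estimation of the phenotypic and genetic variance in height
    explained by a score across age, pubertal-age adjustment of assessment
    ages, family-clustered generalized least squares association for adult
    height, and a synthetic twin-family cohort simulator for validating the
    whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite,
    vcfR
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
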
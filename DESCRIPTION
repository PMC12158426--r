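Package: physage
Title: Physiological Age Clocks, Delta-Age and Gompertz Mortality Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Sex-stratified partial least squares (PLS) clocks that predict
    chronological age from panels of age-sensitive physiological traits,
    age-centered delta-age (predicted minus chronological age), Gompertz
    mortality modelling of the delta-age penalty, covariate-adjusted
    environmental and genotype association scans, healthy-subcohort
    re-testing, and cluster-dropout clock variants that separate global
    aging driver candidates from organ-specific markers.  Includes a
    seeded synthetic cohort generator carrying every statistical
    structure the pipeline assumes (latent aging offsets with genetic and
    environmental determinants, organ-cluster trait correlation,
    follow-up mortality, parental lifespans, missing data) for end-to-end
    validation at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    mixOmics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
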
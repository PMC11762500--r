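Package: alcoscore
Title: Blood DNA Methylation EpiScores and Bayesian Mixture-Model EWAS of
    Alcohol Consumption
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains, projects and evaluates elastic-net DNA methylation
    predictors (EpiScores) of self-reported weekly alcohol consumption under
    feature pre-selection and population-subsetting training designs, and fits
    a Bayesian spike-and-slab mixture regression (BayesR-style Gibbs sampler)
    for joint-conditional epigenome-wide association and methylome variance
    partitioning, with posterior inclusion probabilities and Geweke chain
    diagnostics. Includes a seeded synthetic-cohort generator emulating the
    statistical structure of population methylation studies (sparse CpG effect
    architectures, age/sex/smoking/batch confounding, and discrepancies
    between last-week and habitual intake), an alcohol phenotype preparation
    layer, a phenome association battery with false discovery rate control,
    and an end-to-end reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    glmnet,
    survival,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
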
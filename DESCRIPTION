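Package: devgen
Title: Variance-Component Models for Developmental Quantitative Genetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Maximum-likelihood variance-component inference for cohorts of
    related and unrelated individuals: heritability with empirical or
    pedigree-derived genetic relatedness matrices, bivariate genetic
    correlations, and Gene-by-Age interaction models in which genetic
    variance changes log-linearly with age and the cross-age genetic
    correlation decays exponentially with age difference.  Includes
    boundary-aware likelihood-ratio tests, a confirmatory bifactor /
    hierarchical factor model for binary symptom items with MAP factor
    scoring, trait preparation utilities (chained-equation imputation with
    predictive mean matching, PCA composites, covariate designs,
    rank-based inverse normal transforms), genetic-relatedness-matrix
    construction (pedigree kinship, LD pruning, standardized-dosage GRM),
    and a seeded synthetic-cohort generator (pedigrees, gene-dropped
    genotypes, age-structured phenotypes, binary items) so the whole
    pipeline is testable end to end without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
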
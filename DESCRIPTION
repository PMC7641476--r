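Package: basilnet
Title: Batch Screening Iterative Lasso for Large-Scale Genotype Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes exact lasso and elastic-net regularization paths for
    Gaussian, binomial, and Cox models on PLINK 1 binary genotype data that
    may be too large to hold in memory. The batch screening iterative lasso
    (BASIL) alternates gradient-based batch screening, in-memory
    coordinate-descent fits on a screened strong set, and full-data
    Karush-Kuhn-Tucker certification, so that each iteration needs only one
    full pass over the on-disk genotypes while still returning solutions
    that are exact for the full problem. Includes out-of-core BED access
    with quality-control statistics and mean imputation, unpenalized
    adjustment covariates, the relaxed lasso, validation-based early
    stopping, R-squared and AUC model evaluation, and a synthetic genotype
    and phenotype generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    survival,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    data.table
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse
LinkingTo: Rcpp
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
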
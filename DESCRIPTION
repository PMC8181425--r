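Package: dime
Title: Disease-Gene Immune Cell Expression Networks by Non-Negative Matrix Factorization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Maps curated disease-gene associations onto a reference immune
    cell-type expression matrix (an "immunome") and factorises each disease's
    expression submatrix with Kullback-Leibler non-negative matrix
    factorization (Brunet multiplicative updates, consensus clustering and
    cophenetic model-order selection). Clusters are ranked by the Frobenius
    norm of their rank-one components; top disease-associated cell types and
    genes are taken from the top quartile of the scaled factor weights.
    Includes jackknife stability analysis, pairwise disease comparison through
    common cell-gene networks (Jaccard index and Fisher's exact test), a
    drug-gene interaction overlay that nominates repurposing candidates, and a
    planted-module synthetic data generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
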
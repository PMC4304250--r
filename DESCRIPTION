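Package: nmfsubtypes
Title: Molecular Subtype Discovery by Consensus Non-Negative Matrix
    Factorization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discovers molecular subtypes in bulk gene-expression cohorts
    by KL-divergence non-negative matrix factorization with consensus
    clustering and cophenetic-coefficient rank selection, then
    characterizes the subtypes with Kaplan-Meier and log-rank survival
    comparison, clinicopathologic association tests, SAM-style
    permutation differential expression, and gene set enrichment
    analysis. Includes a synthetic cohort generator with planted
    subtypes, exponential survival and clinical covariates so the whole
    pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    fgsea,
    jsonlite,
    stats,
    survival,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
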
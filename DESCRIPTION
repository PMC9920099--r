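Package: netparafac
Title: Grand-Average Brain Networks via Non-Negative Parallel Factorization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimation of directed functional connectivity networks from
    multichannel time series by squared partial directed coherence (PDC)
    computed from multivariate autoregressive (MVAR) models, and extraction
    of a group-level grand-average network from a population of subject
    networks through a non-negative L1 parallel (CP) factorization with
    minimum-variance selection of the subject loadings. Includes classic
    least-squares PARAFAC for third-order tensors, a synthetic
    swapped-network generator for benchmarking grand-average recovery, and
    a seeded simulation harness reporting false positive rate, false
    negative rate and ROC AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
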
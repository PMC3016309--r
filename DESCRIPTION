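Package: cbpln
Title: Contextual Biological Process Linkage Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores directed links between biological processes (gene sets) over
    a weighted functional interaction network, weighting each linking gene by its
    differential-expression perturbation and by the best confidence-weighted
    perturbation among its neighbors in the source process. Link significance is
    assessed empirically with two permutation null models (annotation-label
    permutation and degree-preserving edge-swap network randomization), corrected
    with the monotone Benjamini-Hochberg procedure, and assembled into a directed
    process-linkage network with interpretable per-link subnetworks. Includes the
    context-free hypergeometric baseline and a synthetic fixture generator with
    planted links for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
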
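Package: netcred
Title: Bayesian Edge-Weight Uncertainty for Animal Social Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates association rates (edge weights) and their uncertainty
    in animal social networks from binary dyadic observation data. Edge
    weights are modelled as beta-distributed association probabilities and
    updated by beta-binomial conjugacy, with the prior fitted to all observed
    dyads by type-II maximum likelihood (empirical Bayes). Frequentist
    comparators are included: the simple ratio index with bootstrap
    confidence intervals obtained by resampling whole sampling periods, and
    exact Clopper-Pearson binomial intervals. Uncertainty is propagated to
    weighted node metrics (strength, eigenvector centrality, betweenness) by
    evaluating metrics over posterior or bootstrap replicate networks. A
    ground-truth network simulator and an evaluation framework (edge error,
    rank correlation, interval false-positive/false-negative rates,
    subsampling reliability curves) support calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
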
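Package: pairedbb
Title: Empirical Bayesian Beta-Binomial Analysis of Paired Sequencing Counts
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects differential expression in paired high-throughput
    sequencing count data using an empirical Bayesian beta-binomial model.
    Counts for one member of a sample pair are modelled as a beta-binomial
    proportion of the pair total, with library-scaling correction. Candidate
    expression patterns are expressed as partitions of the sample pairs;
    marginal likelihoods are approximated by sampling parameter sets from
    the whole data set, model priors are estimated by BIC assignment, and
    false discovery rates are derived from posterior model probabilities.
    Includes a Poisson-mixture simulator (beta or Kumaraswamy biological
    noise) with full truth labels and an ROC evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
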
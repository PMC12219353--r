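Package: pirabias
Title: Bias in Estimated Treatment Effects on Progression Independent of
    Relapse Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect confirmed disability accrual (CDA) events from
    longitudinal Expanded Disability Status Scale (EDSS) trajectories, to
    classify them as progression independent of relapse activity (PIRA) or
    relapse-associated worsening (RAW) under several published definitions
    (Standard1-3, Non-RAW), to extract the relapse-independent component
    (RIC) of a disability trajectory, and to estimate treatment effects on
    PIRA in the never-relapsing principal stratum with a Bayesian mixture
    model. A synthetic two-arm clinical-trial simulator generates EDSS data
    in which relapse-independent and relapse-associated worsening are built
    as separate components, so the true treatment effect on PIRA is known by
    construction and the bias of each estimation strategy can be quantified
    by Monte Carlo simulation with bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
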
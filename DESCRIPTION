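Package: carebundles
Title: Demand-Driven Modular Service Bundles for Community Home-Based
    Older Adult Care
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning community care-demand surveys into
    customized modular service bundles for older adults. Simulates seeded
    survey cohorts with configurable demographic marginals and known
    latent demand effects; computes dimension scores, score rates,
    median/IQR summaries and 75th-percentile activation thresholds; runs
    the nonparametric screening (Mann-Whitney, Kruskal-Wallis) and
    Enter-method dummy-coded multiple regression with collinearity and
    Durbin-Watson diagnostics that yield per-module demand coefficients;
    builds per-person service bundles from binary activation coefficients
    and coefficient-sum weighting factors; classifies priority tiers; and
    monitors delivered bundles with a demand-service matching index whose
    low values trigger automatic module recombination.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    car,
    lmtest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
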
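Package: relaxsel
Title: Trajectories of Antipredator Traits Under Relaxed Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for phylogenetic multilevel meta-analysis of how the mean and
    coefficient of variation of antipredator traits change across generations of
    urbanization, captivity, and domestication. Provides trait harmonization and
    within-study standardization, nonlinear trajectory models (inverse-decay for
    the mean, a Weibull baseline-plus-bump for the coefficient of variation)
    fitted by a covariance matrix adaptation evolution strategy (CMA-ES),
    a Gibbs-sampled Bayesian multilevel meta-regression with phylogenetic,
    species, study, and trait-type random effects and inverse-Wishart variance
    priors, deviance information criterion (DIC) model ranking, heterogeneity
    partitioning (multilevel I-squared) and phylogenetic heritability (H-squared),
    and a synthetic-data generator that emulates the statistical structure of
    such meta-analytic datasets for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
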
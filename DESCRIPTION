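Package: hlamatchr
Title: Simulating and Analysing HLA Match Probability in Unrelated Donor
    Registries for Admixed Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how self-identification, genome-wide genetic
    ancestry and MHC-segment local ancestry affect the probability of
    finding an HLA-matched unrelated stem-cell donor in a registry.
    Provides an HLA allele nomenclature layer (one- and two-field
    resolution, G groups, NMDP-style multiple-allele codes), a seeded
    generator for admixed cohorts and heterogeneously typed donor
    registries, a supervised maximum-likelihood ancestry estimator, an
    indexed multilocus match engine (6/6, 8/8, 10/10 searches with a
    single-allele mismatch allowance), and the match statistics used in
    registry equity analyses: grouped match rates, odds ratios,
    matched-subsample percent decreases, donor-composition averages,
    rank and proportion tests, and the sibling match probability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr
LinkingTo:
    Rcpp
Config/testthat/edition: 3
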
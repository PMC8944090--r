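Package: mrfactors
Title: Two-Sample Mendelian Randomisation of Correlated Reproductive Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying the causal interplay between correlated,
    temporally ordered traits with two-sample Mendelian randomisation.
    Provides a synthetic-cohort generator with a configurable causal DAG over
    eight reproductive-trait analogues (polygenic architecture, shared
    confounding, liability-threshold binary traits, controllable
    exposure/outcome sample overlap), per-SNP association scanning with
    greedy LD clumping, LD score regression for SNP heritability and genetic
    correlation, the full inverse-variance-weighted estimator suite with
    MR-Egger (including SIMEX correction), weighted median and mode,
    MR-PRESSO outlier detection, Steiger directionality tests and filtering,
    multivariable MR, and study-level orchestration: temporal pair plans,
    negative controls, split-sample meta-analysis and report generation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
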
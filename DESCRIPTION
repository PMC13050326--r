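Package: saroc
Title: Safety-Aware ROC Analysis for Clinical Risk Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitions a binary classifier's continuous risk scores into
    Rule-in Safe, Rule-out Safe, and Gray Zones under clinician-defined
    positive and negative predictive value targets, quantifies the
    non-automated workload (Gray Zone Area and Gray-Zone fraction), derives
    operating policies from clinical constraints or utility maximization,
    and characterizes stability via percentile bootstrap and
    prevalence-shift resampling. Includes a Beta-distribution score-cohort
    simulator, ggplot2 visualizations of the safety landscape, and a small
    command-line interface.
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
    tools,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
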
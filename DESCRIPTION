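Package: rowekahn
Title: Rowe-Kahn Successful-Aging Scoring and Self-Rated Health Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the six Rowe-Kahn successful-aging dimensions (absence of
    chronic disease and of disability, good physical and cognitive functioning,
    good interpersonal and productive social engagement) from raw cohort survey
    variables using cohort-relative thresholds, dichotomizes four self-rated
    health and satisfaction outcomes, and estimates prevalences, prevalence
    differences (Wilson and Newcombe score intervals), mutually adjusted
    dimension effects via marginal standardization of logistic models, subgroup
    stratified results, continuum gradients over the 0-6 dimension count, and
    threshold sensitivity analyses. Includes a seeded synthetic two-cohort
    generator with a latent health factor so the whole pipeline is testable
    without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
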
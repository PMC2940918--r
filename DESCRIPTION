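Package: metsburden
Title: Prevalence-Based Cost-of-Illness Modelling of Metabolic Syndrome in
    Hypertension
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An age-, sex- and risk-group structured prevalence-based
    cost-of-illness model for metabolic syndrome in the hypertensive
    population. Classifies subjects against modified ATP III criteria,
    simulates survey-style microdata with a Gaussian-copula dependence
    structure, estimates the joint distribution of metabolic syndrome
    components conditional on hypertension, calibrates it to country-specific
    marginal prevalences by iterative proportional fitting, attributes
    cardiovascular events, mortality and type 2 diabetes to risk groups
    defined by the number of components present, aggregates drug, physician,
    cardiovascular and diabetes costs, projects burden to a horizon year with
    compound annual growth rates, discounts future costs, and runs univariate
    (one-at-a-time) sensitivity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    MASS,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
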
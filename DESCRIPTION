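Package: rifineq
Title: Income-Related Inequality in Binary Health Outcomes via the
    Erreygers Index and RIF Decomposition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for measuring and decomposing household income-related
    inequality in binary health outcomes (activities-of-daily-living,
    instrumental-activities and mobility disability) across multi-country
    ageing surveys.  Implements design-weighted, age-post-stratified
    prevalence estimation with Taylor-linearized confidence intervals,
    weighted fractional income ranks, the standard and Erreygers
    concentration indices with recentred-influence-function (RIF) standard
    errors, a pooled two-level RIF regression decomposition into individual
    and country-level contributors, chained-equation imputation of
    explanatory variables with Rubin pooling, and a synthetic multi-country
    survey generator with known ground-truth inequality for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    MASS,
    nnet,
    sandwich,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
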
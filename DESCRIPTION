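Package: postprandialMR
Title: Observational and One-Sample Mendelian Randomization Analysis of
    BMI Effects on Fasting, Postprandial and Meal-Response Metabolites
Version: 0.1.0
Authors@R:
    person("NEO", "Analyst", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for estimating the effect of body mass
    index (BMI) on metabolite traits measured in the fasting state, in
    the postprandial state after a standardized liquid mixed meal, and
    as a meal-response phenotype derived from Deming (errors-in-both-
    variables) regression residuals. Provides metabolite matrix quality
    control (zero-to-missing conversion, interquartile-range outlier
    screening, bivariate fasting/postprandial outlier removal,
    missingness filters), rank-based inverse normal transformation with
    random tie-breaking, polygenic score construction with GWAS weight
    harmonization, weighted multivariable association models with
    Breusch-Pagan and sequential eta-squared diagnostics, weighted
    two-stage least squares instrumental-variable analysis with
    weak-instrument F and Durbin-Wu-Hausman tests, principal-variable
    clustering to estimate the effective number of independent tests,
    estimate-vector comparison utilities, and a synthetic cohort
    generator emulating a two-subpopulation oversampled study design so
    the whole pipeline is testable without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
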
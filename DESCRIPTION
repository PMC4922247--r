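Package: fieldscope
Title: Linking Laboratory Metabolic Phenotypes to In Situ Fish Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a lab-to-field workflow in fish ecophysiology:
    extraction of standard, maximal and routine metabolic rates (and aerobic
    scope) from intermittent-flow respirometry traces; body-shape (fineness
    ratio), mass-independent metabolic residuals and a principal component
    reduction of secondary metabolic traits; activity metrics (daily distance,
    instantaneous and daily maximal swimming speed, daily buffered track area)
    from high-resolution acoustic telemetry positions; a two-state hidden
    Markov model on step lengths yielding per-fix activity probabilities; and
    random-intercept linear mixed models with fish-specific residual variances,
    AIC/likelihood-ratio model selection and per-fish intraclass correlations.
    A synthetic-data generator emulates the full study design so the pipeline
    is testable end to end without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    nlme,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
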
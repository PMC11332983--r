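Package: hdcohort
Title: Lifetime Markov Cohort Model of Huntington Disease Progression
Version: 0.1.0
Authors@R:
    person("hdcohort", "maintainers", email = "hdcohort@example.org",
           role = c("aut", "cre"))
Description: A decision-analytic state-transition (Markov) cohort model of
    Huntington disease functional decline on the Total Functional Capacity
    (TFC) scale. Annual transition probabilities are derived by simple
    linear regression from short-horizon trajectory data; prefunctional
    cohorts enter active decline through a parametric (logistic) onset
    model stratified by CAG repeat length. The engine accumulates
    discounted and undiscounted life years, quality-adjusted life years
    and stage-specific direct and societal costs over a lifetime horizon,
    evaluates hypothetical disease-modifying treatment scenarios, and
    quantifies uncertainty by probabilistic sensitivity analysis with
    correlated trajectory draws and by one-way (tornado) analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
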
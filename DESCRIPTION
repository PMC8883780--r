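Package: dietsim
Title: Food-Replacement Scenario Simulation and Habitual Protein Intake Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates food-replacement scenarios in two-day 24-hour dietary recall
    survey data: foods with protein content below the 75th percentile of their food
    group are replaced, gram for gram, by a protein-rich or protein-enriched
    alternative from the same group, for participants whose baseline protein intake
    falls below a cut-off (default 1.0 g protein per kg body weight per day).
    Estimates the population distribution of habitual (usual) protein intake from
    the short-term recall data with a one-part shrinkage model that removes
    within-person day-to-day variance (Box-Cox transform, method-of-moments
    variance components, bias-corrected back-transformation by Gauss-Hermite
    quadrature). Includes a seeded synthetic-survey generator calibrated so that a
    target fraction of the population falls below the cut-off, survey-weighted
    nutrient summaries, replacement audit logs, and a combined-scenario derivation
    rule based on food-group contribution rankings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse,
    lme4,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
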
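Package: mpefr
Title: Multiple Predator Effects from Functional Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies multiple predator effects in non-replacement feeding
    trials. Classifies functional response types, fits Rogers' random predator
    equation by maximum likelihood using the Lambert W closed form, predicts
    multi-predator prey depletion from single-predator parameters with a
    population-dynamic model that assumes predator independence, decomposes
    observed interaction strength into trophic and nontrophic components, and
    attaches Latin hypercube sensitivity bands. Includes a stochastic
    feeding-trial generator with optional predator interference, quasi-binomial
    analysis of deviance with backward elimination and Tukey post hoc tests,
    and AICc-based comparison of linear versus quadratic prey-density models.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    deSolve,
    lhs,
    multcomp,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
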
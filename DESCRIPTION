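Package: fedbioage
Title: Federated Biological-Age Modelling and Survival Profiling Across
    Simulated Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates multi-cohort studies of biological age and analyses
    them without pooling participant-level data. Provides a synthetic-cohort
    generator with known ground truth (latent brain-aging and metabolic-aging
    gaps, site effects, survival outcomes), a federated-averaging engine for
    training age predictors across cohorts, fixed-coefficient metabolomic age
    and mortality scorers, linear age-bias correction, federated linear
    regression of score associations with an exact pooled-OLS oracle, and Cox
    proportional-hazards profiling of age-gap quartile combinations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    jsonlite,
    yaml
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
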
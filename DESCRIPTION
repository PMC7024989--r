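Package: phcguideposts
Title: Primary Health Care Investment Guide Posts and Resource Projections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Projects the resources required to strengthen primary health care
    (PHC) across low- and middle-income countries under three nested measures
    of PHC scope. Implements an ingredients-based costing engine (commodities,
    bottom-up workforce requirements, facility infrastructure with
    hospital-share allocation, shared health-system components), coverage
    scale-up trajectories differentiated by health-system maturity with a
    flatline counterfactual, a coverage-effectiveness impact model converting
    scale-up into deaths averted, life-expectancy gains via abridged period
    life tables and healthy life-years, and financing-gap scenario analysis
    (business-as-usual and +1/+2 percentage-point-of-GDP paths). A seeded
    synthetic-country generator emulates the 67-country study cohort so the
    full pipeline is reproducible without restricted inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
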
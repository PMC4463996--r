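Package: dietq
Title: Diet Quality Scoring and Cohort Analytics for FFQ Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates food-group and nutrient intakes from food frequency
    questionnaire (FFQ) style records, screens implausible energy reporters
    with a Schofield-based energy-intake to basal-metabolic-rate ratio,
    scores each diet with an 11-component Healthy Eating Index for
    Australians (HEIFA, 0-100) against the 2013 Australian Dietary
    Guidelines, and reproduces standard cohort analytics: quartile linear
    trends, gender comparisons, guideline-met tallies, and regressions of
    diet quality on sugar-sweetened beverage and takeaway consumption.
    Includes a synthetic-cohort simulator with the statistical structure
    these analyses assume, so every stage is testable without access to
    restricted survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
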
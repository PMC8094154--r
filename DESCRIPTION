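Package: wildmeat
Title: Scenario Analysis of Removing Wild Meat from National Food Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: National-scale scenario analysis of the consequences of removing
    wild meat ("game meat") from food systems. Estimates annual wild-meat
    protein consumption per country from nutrient-supply and food-balance-sheet
    data, the worst-case per-capita protein deficit if that protein is not
    replaced, the agricultural land (pasture and feed cropland) required to
    replace it with domestic livestock, and the consequent species extinctions
    via countryside species-area characterization factors. Includes a seeded
    synthetic-data generator with an independent scalar oracle so the full
    pipeline is testable without external data, and a scenario engine spanning
    the spectrum between the food-insecurity and land-use-change worst cases.
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
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
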
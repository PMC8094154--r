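test_that("read_table validates schemas, headers and rows", {
  expect_error(read_table("x.csv", "not_a_schema"), "unknown schema",
               class = "wm_usage_error")

  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines("country,year,population", tf)
  empty <- read_table(tf, "population")
  expect_equal(nrow(empty), 0)

  writeLines(c("country,year", "XAA,2019"), tf)
  expect_error(read_table(tf, "population"), "population",
               class = "wm_format_error")

  writeLines(c("country,year,population",
               "XAA,2019,0",
               "XAB,2019,5000"), tf)
  expect_warning(ok <- read_table(tf, "population"), "rejected")
  expect_equal(ok$country, "XAB")
  rej <- attr(ok, "rejected")
  expect_equal(rej$row, 1L)
  expect_match(rej$reason, "population must be > 0")
  # no silent drops: accepted + quarantined = input rows
  expect_equal(nrow(ok) + nrow(rej), 2L)
})

test_that("written synthetic tables read back identical", {
  p <- test_panel(12, seed = 3)
  dir <- withr::local_tempdir()
  write_panel_tables(p, dir)
  back <- read_panel_tables(dir)
  expect_setequal(names(back), names(p$inputs))
  for (nm in names(p$inputs)) {
    expect_equal(as.data.frame(back[[nm]]),
                 as.data.frame(p$inputs[[nm]]),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("country name variants resolve to one ISO3 key", {
  expect_equal(resolve_iso3(c("Cote d'Ivoire", "Côte d’Ivoire",
                              "CIV", "XAB")),
               c("CIV", "CIV", "CIV", "XAB"))
  tabs <- list(
    nutrient_supply = tibble::tibble(
      country = c("Cote d'Ivoire"), year = 2011L, P_current = 50,
      animal_protein = 25, W_PPPD = 18),
    population = tibble::tibble(
      country = "Côte d’Ivoire", year = 2019L,
      population = 2.6e7))
  panel <- harmonize_countries(tabs)
  expect_equal(panel$countries, "CIV")
  expect_equal(panel$nutrient$country, "CIV")
  expect_equal(panel$population$country, "CIV")
})

test_that("un-mappable names are quarantined with a warning", {
  tabs <- list(population = tibble::tibble(
    country = c("XAA", "Atlantis"), year = 2019L,
    population = c(1e6, 2e6)))
  expect_warning(panel <- harmonize_countries(tabs), "Atlantis")
  expect_equal(panel$countries, "XAA")
  expect_equal(panel$quarantine$country, "Atlantis")
})

test_that("countries missing an index rank stay in the panel", {
  p <- test_panel(20, seed = 7)
  panel <- harmonize_countries(p$inputs)
  ranked <- p$inputs$food_security_index$country
  unranked <- setdiff(panel$countries, ranked)
  expect_gt(length(unranked), 0)
  expect_true(all(unranked %in% panel$countries))
  expect_false(any(unranked %in% panel$index$country))
})

test_that("missing regional footprints fall back to GLOBAL and log", {
  p <- test_panel(40, seed = 5, missing_region_fraction = 0.3)
  panel <- harmonize_countries(p$inputs)
  orphans <- p$inputs$region_map$country[
    !p$inputs$region_map$region %in% p$inputs$footprints$region]
  expect_gt(length(orphans), 0)
  fb <- panel$footprints[panel$footprints$global_fallback, ]
  expect_setequal(unique(fb$country), orphans)
  expect_true(any(panel$log$stage == "footprint_fallback"))
  # resolution is total: every country has all four sectors resolved
  expect_false(any(is.na(panel$footprints$L_past_m2yr_per_kg)))
})

test_that("nutrient ordering violations are clamped and logged", {
  tabs <- list(
    nutrient_supply = tibble::tibble(
      country = c("XAA", "XAB"), year = 2011L,
      P_current = c(50, 60), animal_protein = c(20, 70),
      W_PPPD = c(25, 10)),
    population = tibble::tibble(country = c("XAA", "XAB"),
                                year = 2019L, population = 1e6))
  panel <- harmonize_countries(tabs)
  expect_equal(panel$nutrient$W_PPPD, c(20, 10))
  expect_equal(panel$nutrient$animal_protein, c(20, 60))
  expect_true(all(c("W_PPPD clamped to animal_protein",
                    "animal_protein clamped to P_current") %in%
                    panel$log$detail))
})

test_that("harmonization is idempotent", {
  p <- test_panel(15, seed = 9)
  once <- harmonize_countries(p$inputs)
  twice <- harmonize_countries(once)
  for (comp in c("countries", "nutrient", "balance", "population",
                 "index", "sector_protein", "footprints", "cfs")) {
    expect_equal(twice[[comp]], once[[comp]])
  }
})

test_that("live weight converts to protein by direct scaling", {
  expect_equal(live_weight_to_protein(0, 0.15), 0)
  expect_equal(live_weight_to_protein(100, 0.20), 20)
  expect_equal(live_weight_to_protein(400, 0.15), 60)
  expect_error(live_weight_to_protein(-1, 0.15),
               class = "wm_domain_error")
  expect_error(live_weight_to_protein(10, 1.5),
               class = "wm_domain_error")
})
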
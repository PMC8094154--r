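test_that("config validation names the offending field", {
  expect_error(synthetic_config(0), "n_countries",
               class = "wm_config_error")
  expect_error(synthetic_config(5, wild_share_range = c(0.5, 0.2)),
               "wild_share_range", class = "wm_config_error")
  expect_error(synthetic_config(5, fao_fraction = 1.5),
               "fao_fraction", class = "wm_config_error")
  expect_error(synthetic_config(5, population_range = c(0, 10)),
               "population_range", class = "wm_config_error")
  expect_error(synthetic_config(5, game_protein_content = 1.2),
               "game_protein_content", class = "wm_config_error")
})

test_that("same config and seed give identical panels and truth", {
  a <- generate_panel(synthetic_config(n_countries = 5, seed = 42))
  b <- generate_panel(synthetic_config(n_countries = 5, seed = 42))
  expect_identical(a$inputs, b$inputs)
  expect_identical(a$truth, b$truth)
  c <- generate_panel(synthetic_config(n_countries = 5, seed = 43))
  expect_false(identical(a$inputs, c$inputs))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(generate_panel(synthetic_config(n_countries = 3, seed = 1)))
  expect_identical(runif(1), before)
})

test_that("zero wild share forces zero consumption", {
  p <- generate_panel(synthetic_config(
    n_countries = 1, seed = 1, wild_share_range = c(0, 0),
    fao_fraction = 0))
  expect_equal(nrow(p$truth$consumption), 0)
  expect_identical(p$truth$excluded, p$inputs$population$country)
})

test_that("generated panels satisfy the structural invariants", {
  p <- test_panel(30, seed = 11)
  nut <- p$inputs$nutrient_supply
  expect_true(all(nut$W_PPPD >= 0))
  expect_true(all(nut$W_PPPD <= nut$animal_protein))
  expect_true(all(nut$animal_protein <= nut$P_current))
  expect_false(anyDuplicated(nut$country) > 0)
  expect_true(all(grepl("^X[A-Z]{2}$", nut$country)))

  shares <- tapply(p$truth$land_by_sector$share,
                   p$truth$land_by_sector$country, sum)
  expect_true(all(abs(shares - 1) < 1e-12))

  bal <- p$inputs$fao_balance
  expect_true(all(bal$production_kg >= 0))
  expect_true(nrow(bal) >= 1)  # fao_fraction = 0.2 over 30 countries
  expect_true(all(nut$W_PPPD[nut$country %in% bal$country] == 0))
})

test_that("oracle reproduces hand arithmetic for one country", {
  inp <- hand_inputs()
  truth <- oracle_outputs(inp, horizon = 10, who_threshold = 50,
                          game_protein_content = 0.15)
  # Eq. 1: 2 g/p/d x 1e6 x 365.25 / 1000
  expect_equal(truth$consumption$W_kg_protein_yr, 730500)
  expect_equal(truth$consumption$source, "GENUS")
  # Eq. 2: 60 - 2
  expect_equal(truth$food_security$P_removal, 58)
  expect_equal(truth$food_security$wild_share, 2 / 30)
  expect_equal(truth$food_security$risk_category, "HIGH_RISK")
  # Eq. 3, single active sector (beef): W x (50 + 10) m2
  expect_equal(truth$land_totals$L_pasture_km2, 730500 * 50 / 1e6)
  expect_equal(truth$land_totals$L_crop_km2, 730500 * 10 / 1e6)
  # Eq. 4 with the worked CF set
  lp <- 730500 * 50 / 1e6
  lc <- 730500 * 10 / 1e6
  expect_equal(truth$biodiversity$B_loss,
               lp * (1e-3 + 10 * 1e-4) + lc * (2e-3 + 10 * 2e-4))
})

test_that("oracle worked example: 1000 kg at 50+10 m2/kg is 0.06 km2", {
  inp <- hand_inputs()
  # Rescale so annual consumption is exactly 1000 kg protein.
  inp$population$population <- 1000 * 1000 / (2 * 365.25)
  truth <- oracle_outputs(inp)
  expect_equal(truth$consumption$W_kg_protein_yr, 1000)
  expect_equal(truth$land_totals$L_total_km2, 0.06)
  expect_equal(truth$land_totals$L_pasture_km2, 0.05)
  expect_equal(truth$land_totals$L_crop_km2, 0.01)
  expect_equal(truth$biodiversity$B_loss,
               0.05 * (1e-3 + 10 * 1e-4) + 0.01 * (2e-3 + 10 * 2e-4))
  expect_equal(truth$biodiversity$B_loss, 1.4e-4)
})

test_that("oracle errors on incomplete reference data", {
  inp <- hand_inputs()
  inp$footprints <- inp$footprints[0, ]
  expect_error(oracle_outputs(inp), "XAA", class = "wm_data_error")
  inp <- hand_inputs()
  inp$characterization_factors <- inp$characterization_factors[0, ]
  expect_error(oracle_outputs(inp), "XAA", class = "wm_data_error")
})
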
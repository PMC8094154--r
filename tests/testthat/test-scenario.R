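scenario_fixture <- function(n = 20, seed = 7) {
  p <- test_panel(n, seed)
  list(p = p, panel = harmonize_countries(p$inputs),
       gpc = p$config$game_protein_content)
}

test_that("scenario specs validate their fractions", {
  expect_error(scenario_spec(1.2, 0), "removal_fraction",
               class = "wm_config_error")
  expect_error(scenario_spec(0.5, -0.1), "substitution_fraction",
               class = "wm_config_error")
  expect_error(scenario_spec(0.5, 0.5, horizon = -1), "horizon",
               class = "wm_config_error")
  expect_error(scenario_spec(0.5, 0.5, who_threshold = 0),
               "who_threshold", class = "wm_config_error")
})

test_that("business as usual changes nothing", {
  fx <- scenario_fixture()
  res <- run_scenario(fx$panel, scenario_spec(0, 0.5),
                      game_protein_content = fx$gpc)
  expect_true(all(res$countries$deficit_gppd == 0))
  expect_true(all(res$countries$P_effective ==
                    res$countries$P_current))
  expect_true(all(res$countries$L_total_km2 == 0))
  expect_true(all(res$countries$B_loss == 0))
  expect_equal(res$totals$L_total_km2, 0)
  expect_equal(res$totals$B_loss, 0)
})

test_that("full removal without substitution is the food-insecurity endpoint", {
  fx <- scenario_fixture()
  res <- run_scenario(fx$panel, scenario_spec(1, 0),
                      game_protein_content = fx$gpc)
  cons <- estimate_consumption(fx$panel, game_protein_content = fx$gpc)
  fs <- assess_food_security(fx$panel, cons, who_threshold = 50)
  expect_equal(res$countries$country, fs$country)
  expect_equal(res$countries$P_effective, fs$P_removal)
  expect_equal(res$countries$share_at_risk, fs$wild_share)
  expect_identical(res$countries$below_who, fs$below_who)
  expect_identical(res$countries$risk_category, fs$risk_category)
  expect_true(all(res$countries$L_total_km2 == 0))
})

test_that("full removal with full substitution is the land-use endpoint", {
  fx <- scenario_fixture()
  res <- run_scenario(fx$panel, scenario_spec(1, 1),
                      game_protein_content = fx$gpc)
  cons <- estimate_consumption(fx$panel, game_protein_content = fx$gpc)
  land <- land_demand_all(fx$panel, cons)
  bl <- biodiversity_loss(land$totals, fx$panel$cfs, horizon = 10)
  expect_equal(res$countries$L_total_km2, land$totals$L_total_km2)
  expect_equal(res$countries$L_pasture_km2, land$totals$L_pasture_km2)
  expect_equal(res$countries$B_loss, bl$B_loss)
  # protein-neutral identity: supplies return to current levels
  expect_true(all(res$countries$deficit_gppd == 0))
  expect_equal(res$countries$P_effective, res$countries$P_current)
})

test_that("deficit and land demand are bilinear in (r, f)", {
  fx <- scenario_fixture()
  cons <- estimate_consumption(fx$panel, game_protein_content = fx$gpc)
  land1 <- land_demand_all(fx$panel, cons)$totals$L_total_km2
  fs <- assess_food_security(fx$panel, cons, who_threshold = 50)
  w <- fs$W_PPPD_g
  for (r in c(0, 0.25, 0.5, 0.75, 1)) {
    for (f in c(0, 0.25, 0.5, 0.75, 1)) {
      res <- run_scenario(fx$panel, scenario_spec(r, f),
                          game_protein_content = fx$gpc)
      expect_equal(res$countries$deficit_gppd, (1 - f) * r * w,
                   tolerance = 1e-12)
      expect_equal(res$countries$L_total_km2, f * r * land1,
                   tolerance = 1e-12)
    }
  }
  # spot-check the half-way interpolation against the endpoints
  half <- run_scenario(fx$panel, scenario_spec(1, 0.5),
                       game_protein_content = fx$gpc)
  expect_equal(half$countries$L_total_km2, 0.5 * land1)
  expect_equal(half$countries$deficit_gppd, 0.5 * w)
})

test_that("global totals are sums over countries", {
  fx <- scenario_fixture()
  res <- run_scenario(fx$panel, scenario_spec(1, 1),
                      game_protein_content = fx$gpc)
  x <- res$countries
  expect_equal(res$totals$L_total_km2, sum(x$L_total_km2))
  expect_equal(res$totals$B_loss, sum(x$B_loss))
  expect_equal(res$totals$n_countries, nrow(x))
  # and match the independent oracle on the same panel
  expect_true(rel_err(res$totals$L_total_km2,
                      fx$p$truth$totals$L_total_km2) < 1e-9)
  expect_true(rel_err(res$totals$B_loss,
                      fx$p$truth$totals$B_loss) < 1e-9)
  # hand-summed two-country check
  two <- x[1:2, ]
  expect_equal(two$L_total_km2[1] + two$L_total_km2[2],
               sum(two$L_total_km2))
})
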
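test_that("replacement shares follow current meat consumption", {
  s <- sector_shares(c(poultry = 20, beef = 30, pork = 50,
                       sheep_goat = 0))
  expect_equal(s[["poultry"]], 0.20)
  expect_equal(s[["beef"]], 0.30)
  expect_equal(s[["pork"]], 0.50)
  expect_equal(s[["sheep_goat"]], 0)
  expect_equal(sum(s), 1)

  single <- sector_shares(c(beef = 7))
  expect_equal(single[["beef"]], 1)
  expect_equal(sum(single), 1)

  expect_warning(eq <- sector_shares(c(beef = 0, pork = 0)), "equal")
  expect_equal(unname(eq), rep(0.25, 4))
  expect_error(sector_shares(c(beef = -1)), class = "wm_domain_error")
  expect_error(sector_shares(c(veal = 3)), class = "wm_usage_error")
})

test_that("land demand reproduces the worked examples", {
  fp1 <- tibble::tibble(sector = "beef", L_past_m2yr_per_kg = 50,
                        L_crop_m2yr_per_kg = 10)
  zero <- land_demand(0, c(beef = 1), fp1)
  expect_equal(attr(zero, "L_total_km2"), 0)
  expect_equal(zero$pasture_km2, c(0))

  one <- land_demand(1000, c(beef = 1), fp1)
  expect_equal(attr(one, "L_total_km2"), 0.06)
  expect_equal(attr(one, "L_pasture_km2"), 0.05)
  expect_equal(attr(one, "L_crop_km2"), 0.01)

  fp2 <- tibble::tibble(
    sector = c("beef", "poultry"),
    L_past_m2yr_per_kg = c(200, 0),
    L_crop_m2yr_per_kg = c(20, 12))
  mixed <- land_demand(1000, c(beef = 0.3, poultry = 0.7), fp2)
  expect_equal(attr(mixed, "L_total_km2"), 0.0744)
})

test_that("land demand errors when an active sector has no footprint", {
  fp <- tibble::tibble(sector = "beef", L_past_m2yr_per_kg = 50,
                       L_crop_m2yr_per_kg = 10)
  expect_error(land_demand(10, c(beef = 0.5, pork = 0.5), fp),
               "pork", class = "wm_data_error")
})

test_that("land demand is homogeneous and convex in shares", {
  fp <- tibble::tibble(
    sector = c("beef", "sheep_goat", "pork", "poultry"),
    L_past_m2yr_per_kg = c(1200, 900, 30, 8),
    L_crop_m2yr_per_kg = c(150, 90, 500, 400))
  shares <- c(beef = 0.1, sheep_goat = 0.2, pork = 0.3, poultry = 0.4)
  base <- attr(land_demand(1000, shares, fp), "L_total_km2")
  for (k in c(0, 0.25, 3)) {
    expect_equal(attr(land_demand(k * 1000, shares, fp),
                      "L_total_km2"), k * base)
  }
  # share-weighted sum of single-sector demands equals the mixture
  singles <- vapply(names(shares), function(s) {
    one <- setNames(rep(0, 4), names(shares))
    one[s] <- 1
    attr(land_demand(1000, one, fp), "L_total_km2")
  }, numeric(1))
  expect_equal(sum(shares * singles), base)
  # units round-trip: km2 back to m2 is lossless
  out <- land_demand(1000, shares, fp)
  m2 <- (out$pasture_km2 + out$cropland_km2) * 1e6
  direct <- shares * 1000 * (fp$L_past_m2yr_per_kg +
                               fp$L_crop_m2yr_per_kg)
  expect_true(all(rel_err(m2, unname(direct)) < 1e-9))
})

test_that("panel-level land demand matches the scalar oracle", {
  p <- test_panel(30, seed = 17)
  panel <- harmonize_countries(p$inputs)
  cons <- estimate_consumption(
    panel, game_protein_content = p$config$game_protein_content)
  land <- land_demand_all(panel, cons)
  truth <- p$truth$land_totals
  expect_equal(land$totals$country, truth$country)
  for (col in c("L_pasture_km2", "L_crop_km2", "L_total_km2")) {
    expect_true(all(rel_err(land$totals[[col]], truth[[col]]) < 1e-9))
  }
  # per-sector decomposition sums to the totals
  sums <- tapply(land$by_sector$pasture_km2 +
                   land$by_sector$cropland_km2,
                 land$by_sector$country, sum)
  expect_true(all(rel_err(as.numeric(sums[land$totals$country]),
                          land$totals$L_total_km2) < 1e-9))
})
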
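# Shared fixtures: memoised synthetic panels and a tiny hand-built
# input set whose outputs are easy to compute by hand.

.fixture_env <- new.env(parent = emptyenv())

test_panel <- function(n = 20, seed = 7, ...) {
  key <- paste0("p", n, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    cfg <- synthetic_config(n_countries = n, seed = seed, ...)
    .fixture_env[[key]] <- generate_panel(cfg)
  }
  .fixture_env[[key]]
}

rel_err <- function(x, y) {
  ifelse(y == 0, abs(x), abs(x / y - 1))
}

# One country, one active sector, round numbers:
#   W_PPPD = 2 g/p/d, pop = 1e6 -> W = 730,500 kg protein/yr.
hand_inputs <- function() {
  list(
    nutrient_supply = tibble::tibble(
      country = "XAA", year = 2011L, P_current = 60,
      animal_protein = 30, W_PPPD = 2),
    fao_balance = tibble::tibble(
      country = character(), production_kg = double(),
      imports_kg = double(), exports_kg = double()),
    population = tibble::tibble(country = "XAA", year = 2019L,
                                population = 1e6),
    food_security_index = tibble::tibble(country = "XAA", rank = 84L,
                                         n_ranked = 113L),
    footprints = tibble::tibble(
      region = "GLOBAL", sector = wildmeat:::WM_SECTORS,
      L_past_m2yr_per_kg = c(50, 40, 5, 1),
      L_crop_m2yr_per_kg = c(10, 8, 60, 45),
      protein_content = 0.15),
    characterization_factors = tibble::tibble(
      country = "XAA", C_past = 1e-3, C_crop = 2e-3,
      O_past = 1e-4, O_crop = 2e-4),
    sector_protein = tibble::tibble(
      country = "XAA", sector = wildmeat:::WM_SECTORS,
      protein_gppd = c(7, 0, 0, 0)),
    region_map = tibble::tibble(country = "XAA", region = "GLOBAL")
  )
}
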
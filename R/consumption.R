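#' Annualise per-capita daily wild-meat protein supply
#'
#' National annual wild-meat protein consumption from the
#' nutrient-supply path: `W = W_PPPD x population x 365.25 / 1000`
#' (grams per person per day to kg per country per year).
#'
#' @param w_pppd Wild-meat protein supply, g/person/day (vectorised).
#' @param population Persons (`> 0`).
#' @return kg wild-meat protein per year.
#' @examples
#' annual_consumption_genus(2, 10000) # 7305 kg/yr
#' @export
annual_consumption_genus <- function(w_pppd, population) {
  if (any(w_pppd < 0)) {
    abort("w_pppd must be >= 0", class = "wm_domain_error")
  }
  if (any(population <= 0)) {
    abort("population must be > 0", class = "wm_domain_error")
  }
  w_pppd * population * WM_DAYS_PER_YEAR / 1000
}

#' Apparent consumption from a food balance sheet
#'
#' Apparent live-weight consumption is national production plus the
#' trade balance (imports minus exports). Re-export artifacts can make
#' this negative; such values are clamped to zero with a warning, never
#' an error.
#'
#' @param production,imports,exports kg live weight per year
#'   (vectorised, `>= 0`).
#' @return Apparent consumption, kg live weight per year.
#' @export
apparent_live_weight <- function(production, imports, exports) {
  if (any(production < 0) || any(imports < 0) || any(exports < 0)) {
    abort("balance-sheet quantities must be >= 0",
          class = "wm_domain_error")
  }
  apparent <- production + imports - exports
  neg <- apparent < 0
  if (any(neg)) {
    warn(paste0(sum(neg), " balance-sheet record(s) with negative ",
                "apparent consumption clamped to 0"))
    apparent[neg] <- 0
  }
  apparent
}

#' Annual wild-meat protein from the balance-sheet path
#'
#' Converts apparent live-weight consumption
#' (see [apparent_live_weight()]) to protein mass.
#'
#' @inheritParams apparent_live_weight
#' @param protein_content kg protein per kg live weight, in `(0, 1)`.
#' @return kg wild-meat protein per year.
#' @examples
#' annual_consumption_fao(500, 200, 300, 0.15) # 60 kg protein/yr
#' @export
annual_consumption_fao <- function(production, imports, exports,
                                   protein_content) {
  live_weight_to_protein(
    apparent_live_weight(production, imports, exports), protein_content)
}

#' Merge nutrient-supply and balance-sheet consumption estimates
#'
#' The nutrient-supply (GENuS-path) estimate takes precedence; the
#' balance-sheet (FAO-path) estimate fills countries absent from the
#' nutrient-supply source or — when `genus_zero_is_gap` — reporting
#' exactly zero there. Countries with zero consumption under both
#' sources are excluded from downstream stages and listed in the
#' `"excluded"` attribute (the non-zero-estimates filter).
#'
#' @param genus,fao Tibbles with columns `country, W_kg_protein_yr,
#'   W_PPPD_g, live_weight_kg, source`.
#' @param genus_zero_is_gap Treat an exactly-zero nutrient-supply value
#'   as a gap to be filled from the balance sheet (default `TRUE`).
#' @return One-estimate-per-country tibble (same columns), ISO3
#'   ascending, `W_kg_protein_yr > 0` everywhere; attribute
#'   `"excluded"` holds the zero-consumption countries.
#' @export
merge_consumption <- function(genus, fao, genus_zero_is_gap = TRUE) {
  cols <- c("country", "W_kg_protein_yr", "W_PPPD_g",
            "live_weight_kg", "source")
  empty <- tibble(country = character(), W_kg_protein_yr = double(),
                  W_PPPD_g = double(), live_weight_kg = double(),
                  source = character())
  genus <- if (is.null(genus)) empty else as_tibble(genus)[cols]
  fao <- if (is.null(fao)) empty else as_tibble(fao)[cols]
  stopifnot(!anyDuplicated(genus$country), !anyDuplicated(fao$country))

  genus_kept <- if (genus_zero_is_gap) {
    genus[genus$W_kg_protein_yr > 0, ]
  } else {
    genus
  }
  fao_fill <- fao[!(fao$country %in% genus_kept$country), ]
  merged <- bind_rows(genus_kept, fao_fill) |>
    arrange(.data$country)
  excluded <- setdiff(unique(c(genus$country, fao$country)),
                      merged$country[merged$W_kg_protein_yr > 0])
  merged <- filter(merged, .data$W_kg_protein_yr > 0)
  attr(merged, "excluded") <- sort(excluded)
  merged
}

#' Estimate national wild-meat consumption for a panel
#'
#' Runs both estimation paths over a harmonized panel and merges them:
#' the nutrient-supply path annualises `W_PPPD` (Eq. 1 style), the
#' balance-sheet path converts apparent live-weight consumption to
#' protein and back-derives a per-capita daily value
#' (`W / population / 365.25 x 1000`).
#'
#' @param panel A `country_panel` from [harmonize_countries()].
#' @param game_protein_content kg protein per kg live weight used for
#'   the balance-sheet conversion (default 0.15).
#' @param genus_zero_is_gap See [merge_consumption()].
#' @return See [merge_consumption()].
#' @export
estimate_consumption <- function(panel, game_protein_content = 0.15,
                                 genus_zero_is_gap = TRUE) {
  stopifnot(inherits(panel, "country_panel"))
  pop <- panel$population
  if (is.null(pop) || nrow(pop) == 0) {
    abort("panel has no population records", class = "wm_data_error")
  }
  genus <- NULL
  if (!is.null(panel$nutrient) && nrow(panel$nutrient) > 0) {
    genus <- panel$nutrient |>
      inner_join(select(pop, "country", "population"), by = "country") |>
      mutate(
        W_kg_protein_yr = annual_consumption_genus(.data$W_PPPD,
                                                   .data$population),
        W_PPPD_g = .data$W_PPPD,
        live_weight_kg = NA_real_,
        source = "GENUS"
      ) |>
      select("country", "W_kg_protein_yr", "W_PPPD_g",
             "live_weight_kg", "source")
  }
  fao <- NULL
  if (!is.null(panel$balance) && nrow(panel$balance) > 0) {
    fao <- panel$balance |>
      inner_join(select(pop, "country", "population"), by = "country") |>
      mutate(
        live_weight_kg = apparent_live_weight(.data$production_kg,
                                              .data$imports_kg,
                                              .data$exports_kg),
        W_kg_protein_yr = .data$live_weight_kg * game_protein_content,
        W_PPPD_g = .data$W_kg_protein_yr / .data$population /
          WM_DAYS_PER_YEAR * 1000,
        source = "FAO"
      ) |>
      select("country", "W_kg_protein_yr", "W_PPPD_g",
             "live_weight_kg", "source")
  }
  merge_consumption(genus, fao, genus_zero_is_gap = genus_zero_is_gap)
}
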
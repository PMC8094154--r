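#' Specify a removal/substitution scenario
#'
#' A point on the spectrum between the two worst cases: a fraction
#' \eqn{r} of wild meat is removed from diets, and a fraction \eqn{f}
#' of the removed protein is replaced by livestock production.
#' \eqn{r = 0} is business as usual; \eqn{(r = 1, f = 0)} is the
#' food-insecurity endpoint (all wild meat lost, nothing replaced);
#' \eqn{(r = 1, f = 1)} is the land-use-change endpoint (all wild meat
#' replaced by animal agriculture, the protein-neutral line).
#'
#' @param removal_fraction Fraction of wild meat removed, in `[0, 1]`.
#' @param substitution_fraction Fraction of removed protein replaced by
#'   livestock, in `[0, 1]`.
#' @param horizon Occupation horizon in years for the biodiversity
#'   stage (default 10).
#' @param who_threshold WHO recommended minimum protein intake,
#'   g/person/day (default 50).
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(removal_fraction, substitution_fraction,
                          horizon = 10, who_threshold = 50) {
  for (nm in c("removal_fraction", "substitution_fraction")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      abort(paste0("invalid scenario field '", nm,
                   "': must be a single value in [0, 1]"),
            class = "wm_config_error")
    }
  }
  if (!is.numeric(horizon) || length(horizon) != 1 || horizon < 0) {
    abort("invalid scenario field 'horizon': must be >= 0",
          class = "wm_config_error")
  }
  if (!is.numeric(who_threshold) || length(who_threshold) != 1 ||
      who_threshold <= 0) {
    abort("invalid scenario field 'who_threshold': must be > 0",
          class = "wm_config_error")
  }
  structure(list(removal_fraction = removal_fraction,
                 substitution_fraction = substitution_fraction,
                 horizon = horizon, who_threshold = who_threshold),
            class = "scenario_spec")
}

#' Run a removal/substitution scenario over a panel
#'
#' For each country with non-zero wild-meat consumption: the removed
#' per-capita protein is \eqn{r \times W_{PPPD}}; the unreplaced part
#' \eqn{(1 - f) r W_{PPPD}} is subtracted from current protein supply
#' (the food-insecurity calculation applied to the effective deficit);
#' the replaced part \eqn{f r W} is fed through the land-demand and
#' biodiversity stages. WHO and risk flags are recomputed on the
#' effective deficit, so \eqn{(r = 1, f = 0)} reproduces the
#' food-security stage and \eqn{(r = 1, f = 1)} the land and
#' biodiversity stages exactly.
#'
#' @param panel A `country_panel`.
#' @param spec A [scenario_spec()].
#' @param game_protein_content kg protein per kg live weight for the
#'   balance-sheet path (default 0.15).
#' @return A `scenario_result` list: `spec`, `countries` (per-country
#'   tibble with deficit, land and biodiversity columns), `by_sector`
#'   (per-country-sector land), and `totals` (see [global_totals()]).
#' @export
run_scenario <- function(panel, spec, game_protein_content = 0.15) {
  stopifnot(inherits(panel, "country_panel"),
            inherits(spec, "scenario_spec"))
  r <- spec$removal_fraction
  f <- spec$substitution_fraction

  consumption <- estimate_consumption(
    panel, game_protein_content = game_protein_content)

  base <- consumption |>
    inner_join(select(panel$nutrient, "country", "P_current",
                      "animal_protein"), by = "country")
  over <- base$W_PPPD_g > base$animal_protein
  if (any(over)) {
    warn(paste0("back-derived W_PPPD exceeds animal protein for ",
                paste(base$country[over], collapse = ", "),
                "; clamped"))
    base$W_PPPD_g[over] <- base$animal_protein[over]
  }

  idx <- if (!is.null(panel$index)) panel$index else
    tibble(country = character(), rank = integer(),
           n_ranked = integer())

  fs <- base |>
    mutate(
      removed_pppd = r * .data$W_PPPD_g,
      deficit_gppd = (1 - f) * r * .data$W_PPPD_g,
      P_effective = .data$P_current - .data$deficit_gppd,
      share_at_risk = wild_share(.data$deficit_gppd,
                                 .data$animal_protein),
      below_who = flag_below_who(.data$P_effective,
                                 spec$who_threshold)
    ) |>
    left_join(select(idx, "country", "rank", "n_ranked"),
              by = "country") |>
    mutate(risk_category = classify_risk(.data$share_at_risk,
                                         .data$rank, .data$n_ranked))

  replaced <- consumption
  replaced$W_kg_protein_yr <- f * r * replaced$W_kg_protein_yr
  land <- land_demand_all(panel, replaced)
  bloss <- biodiversity_loss(land$totals, panel$cfs,
                             horizon = spec$horizon)

  countries <- fs |>
    select("country", "source", "W_kg_protein_yr", "W_PPPD_g",
           "P_current", "removed_pppd", "deficit_gppd", "P_effective",
           "share_at_risk", "below_who", "risk_category", "rank",
           "n_ranked") |>
    left_join(land$totals, by = "country") |>
    left_join(select(bloss, "country", "one_off", "occupation",
                     "B_loss"), by = "country") |>
    arrange(.data$country)

  result <- structure(list(spec = spec, countries = countries,
                           by_sector = land$by_sector),
                      class = "scenario_result")
  result$totals <- global_totals(result)
  result
}

#' Aggregate a scenario result to global totals
#'
#' @param result A `scenario_result` from [run_scenario()].
#' @return One-row tibble: country count, summed land areas (km2),
#'   summed species loss, and counts of below-WHO and high-risk
#'   countries.
#' @export
global_totals <- function(result) {
  stopifnot(inherits(result, "scenario_result"))
  x <- result$countries
  tibble(
    n_countries = nrow(x),
    L_pasture_km2 = sum(x$L_pasture_km2),
    L_crop_km2 = sum(x$L_crop_km2),
    L_total_km2 = sum(x$L_total_km2),
    B_loss = sum(x$B_loss),
    n_below_who = sum(x$below_who),
    n_high_risk = sum(x$risk_category == "HIGH_RISK"),
    n_unranked = sum(x$risk_category == "UNRANKED")
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result> r = ", x$spec$removal_fraction,
      ", f = ", x$spec$substitution_fraction,
      ", horizon = ", x$spec$horizon, " yr\n", sep = "")
  cat("  countries: ", nrow(x$countries),
      "; total land ", format(x$totals$L_total_km2, digits = 6),
      " km2; species loss ", format(x$totals$B_loss, digits = 6),
      "\n", sep = "")
  invisible(x)
}
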
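#' Risk-landscape table (consumption vs food-insecurity rank)
#'
#' One row per country possessing both a consumption estimate and a
#' food-security rank: per-capita wild-meat protein on x, rank on y,
#' species loss as the size variable, with the WHO and high-risk
#' flags. Countries without a rank are returned in a side table,
#' never silently dropped. Rows are ordered ISO3 ascending.
#'
#' @param assessment Output of [assess_food_security()].
#' @param losses Output of [biodiversity_loss()].
#' @return List with `landscape` (tibble `country, x_w_pppd_g,
#'   y_rank, size_b_loss, below_who, high_risk`) and `unranked`
#'   (tibble `country, reason`).
#' @export
risk_landscape <- function(assessment, losses) {
  ranked <- filter(assessment, !is.na(.data$rank))
  unranked <- filter(assessment, is.na(.data$rank))
  landscape <- ranked |>
    left_join(select(losses, "country", "B_loss"), by = "country") |>
    mutate(
      x_w_pppd_g = .data$W_PPPD_g,
      y_rank = .data$rank,
      size_b_loss = dplyr::coalesce(.data$B_loss, 0),
      high_risk = .data$risk_category == "HIGH_RISK"
    ) |>
    select("country", "x_w_pppd_g", "y_rank", "size_b_loss",
           "below_who", "high_risk") |>
    arrange(.data$country)
  list(
    landscape = landscape,
    unranked = tibble(country = sort(unranked$country),
                      reason = "no food-security rank")
  )
}

#' National summary table
#'
#' One row per country with the outputs of every stage — consumption,
#' worst-case deficit, land demand, biodiversity loss — plus a
#' `TOTAL` footer row holding the global sums (flag columns hold
#' counts in the footer).
#'
#' @param consumption Output of [estimate_consumption()].
#' @param assessment Output of [assess_food_security()].
#' @param land Output of [land_demand_all()].
#' @param losses Output of [biodiversity_loss()].
#' @return Tibble, ISO3 ascending with the footer last.
#' @export
national_table <- function(consumption, assessment, land, losses) {
  wide_sectors <- land$by_sector |>
    pivot_wider(id_cols = "country", names_from = "sector",
                values_from = c("pasture_km2", "cropland_km2"))
  rows <- consumption |>
    left_join(select(assessment, "country", "P_current", "P_removal",
                     "wild_share", "below_who", "risk_category"),
              by = "country") |>
    left_join(wide_sectors, by = "country") |>
    left_join(land$totals, by = "country") |>
    left_join(select(losses, "country", "one_off", "occupation",
                     "B_loss"), by = "country") |>
    arrange(.data$country)
  num_cols <- names(rows)[vapply(rows, is.numeric, logical(1))]
  footer <- rows |>
    summarise(across(dplyr::all_of(num_cols), \(v) sum(v, na.rm = TRUE)))
  footer$country <- "TOTAL"
  footer$source <- NA_character_
  footer$risk_category <- NA_character_
  # In the footer the flag column carries the count of flagged
  # countries; per-capita columns are left as sums and should not be
  # interpreted.
  footer$below_who <- sum(rows$below_who, na.rm = TRUE)
  rows$below_who <- as.numeric(rows$below_who)
  bind_rows(rows, footer)
}

#' Run report
#'
#' Collects the audit trail of a pipeline run: configuration values,
#' clamps and fallbacks logged during harmonization, quarantined rows,
#' and the countries excluded by the non-zero-consumption filter or
#' skipped for missing records.
#'
#' @param panel A `country_panel`.
#' @param consumption Output of [estimate_consumption()].
#' @param assessment Output of [assess_food_security()].
#' @return A list suitable for JSON serialisation.
#' @export
run_report <- function(panel, consumption, assessment) {
  list(
    n_countries = length(panel$countries),
    n_consumption = nrow(consumption),
    who_threshold = attr(assessment, "who_threshold"),
    excluded_zero_consumption = attr(consumption, "excluded"),
    skipped_no_nutrient = attr(assessment, "skipped"),
    quarantine = panel$quarantine,
    log = panel$log
  )
}

#' Write the standard output files for a pipeline run
#'
#' Writes `national_summary.csv`, `risk_landscape.csv`,
#' `risk_landscape_unranked.csv` and `run_report.json` under `dir`.
#'
#' @param dir Output directory (created if absent).
#' @inheritParams national_table
#' @param panel A `country_panel` (for the run report).
#' @return Invisibly, the vector of paths written.
#' @export
write_outputs <- function(dir, panel, consumption, assessment, land,
                          losses) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nat <- national_table(consumption, assessment, land, losses)
  rl <- risk_landscape(assessment, losses)
  paths <- c(
    file.path(dir, "national_summary.csv"),
    file.path(dir, "risk_landscape.csv"),
    file.path(dir, "risk_landscape_unranked.csv"),
    file.path(dir, "run_report.json")
  )
  readr::write_csv(nat, paths[1])
  readr::write_csv(rl$landscape, paths[2])
  readr::write_csv(rl$unranked, paths[3])
  jsonlite::write_json(run_report(panel, consumption, assessment),
                       paths[4], auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(paths)
}
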
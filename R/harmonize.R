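#' Built-in country-name alias map
#'
#' Country identifiers are canonicalised to ISO3 codes before any join.
#' Strings that already look like ISO3 codes (three upper-case letters,
#' including the reserved synthetic `"X.."` namespace) pass through;
#' everything else is matched, after accent- and punctuation-folding,
#' against this alias table. Users can extend it via the `alias_extra`
#' argument of [harmonize_countries()].
#'
#' @return A tibble with columns `alias` and `iso3`.
#' @export
country_alias_map <- function() {
  tibble(
    alias = c(
      "cote divoire", "cote d ivoire", "ivory coast",
      "republic of congo", "congo", "congo rep", "congo brazzaville",
      "democratic republic of the congo", "congo dem rep", "dr congo",
      "central african republic",
      "united states", "united states of america", "usa",
      "united kingdom", "great britain",
      "tanzania", "united republic of tanzania",
      "bolivia", "bolivia plurinational state of",
      "venezuela", "venezuela bolivarian republic of",
      "russia", "russian federation",
      "south korea", "republic of korea",
      "laos", "lao peoples democratic republic",
      "vietnam", "viet nam",
      "myanmar", "burma",
      "cape verde", "cabo verde",
      "swaziland", "eswatini",
      "madagascar", "botswana", "guinea", "rwanda", "zimbabwe",
      "nigeria", "brazil", "ecuador", "colombia", "ethiopia",
      "cameroon", "suriname", "new zealand", "malawi", "ghana", "gabon",
      "china"
    ),
    iso3 = c(
      "CIV", "CIV", "CIV",
      "COG", "COG", "COG", "COG",
      "COD", "COD", "COD",
      "CAF",
      "USA", "USA", "USA",
      "GBR", "GBR",
      "TZA", "TZA",
      "BOL", "BOL",
      "VEN", "VEN",
      "RUS", "RUS",
      "KOR", "KOR",
      "LAO", "LAO",
      "VNM", "VNM",
      "MMR", "MMR",
      "CPV", "CPV",
      "SWZ", "SWZ",
      "MDG", "BWA", "GIN", "RWA", "ZWE",
      "NGA", "BRA", "ECU", "COL", "ETH",
      "CMR", "SUR", "NZL", "MWI", "GHA", "GAB",
      "CHN"
    )
  )
}

.wm_fold_name <- function(x) {
  # Accent- and punctuation-fold to bare letters so spelling variants
  # ("Cote d'Ivoire", "Côte d’Ivoire") collapse to one key.
  x <- iconv(x, from = "UTF-8", to = "ASCII//TRANSLIT")
  x <- tolower(x)
  gsub("[^a-z]", "", x)
}

#' Resolve country identifiers to ISO3
#'
#' @param x Character vector of country names or codes.
#' @param alias_extra Optional tibble of extra `alias`, `iso3` pairs
#'   that take precedence over the built-in map.
#' @return Character vector of ISO3 codes, `NA` where unresolvable.
#' @export
resolve_iso3 <- function(x, alias_extra = NULL) {
  map <- country_alias_map()
  if (!is.null(alias_extra)) {
    map <- bind_rows(as_tibble(alias_extra)[, c("alias", "iso3")], map)
  }
  map$alias <- .wm_fold_name(map$alias)
  map <- map[!duplicated(map$alias), ]
  out <- rep(NA_character_, length(x))
  is_code <- grepl("^[A-Z]{3}$", x)
  out[is_code] <- x[is_code]
  idx <- match(.wm_fold_name(x[!is_code]), map$alias)
  out[!is_code] <- map$iso3[idx]
  out
}

#' Convert live weight to protein mass
#'
#' Balance-sheet game-meat quantities are reported as live weight;
#' the analysis runs on protein, so live weight is scaled by a protein
#' content fraction taken from life-cycle-assessment data or
#' configuration.
#'
#' @param mass Live weight, kg (vectorised, must be `>= 0`).
#' @param protein_content kg protein per kg live weight, in `(0, 1)`.
#' @return Protein mass, kg.
#' @examples
#' live_weight_to_protein(400, 0.15) # 60 kg protein
#' @export
live_weight_to_protein <- function(mass, protein_content) {
  if (any(mass < 0)) abort("mass must be >= 0", class = "wm_domain_error")
  if (any(protein_content <= 0 | protein_content >= 1)) {
    abort("protein_content must be in (0, 1)", class = "wm_domain_error")
  }
  mass * protein_content
}

.wm_resolve_key <- function(tab, what, alias_extra, quarantine) {
  if (is.null(tab) || nrow(tab) == 0) {
    return(list(tab = tab, quarantine = quarantine))
  }
  iso <- resolve_iso3(tab$country, alias_extra)
  bad <- is.na(iso)
  if (any(bad)) {
    quarantine <- bind_rows(quarantine, tibble(
      table = what, country = tab$country[bad],
      reason = "un-mappable country name"))
    warn(paste0("quarantined ", sum(bad), " row(s) of '", what,
                "' with un-mappable country name(s): ",
                paste(unique(tab$country[bad]), collapse = ", ")))
  }
  tab <- tab[!bad, ]
  tab$country <- iso[!bad]
  list(tab = tab, quarantine = quarantine)
}

#' Harmonize input tables into a country panel
#'
#' Merges the input tables into one record per country: identifiers are
#' resolved to ISO3, nutrient-supply ordering violations
#' (`W_PPPD <= animal_protein <= P_current`) are clamped to the binding
#' bound and logged, populations are reduced to the reference year, and
#' every country is given a resolved land footprint per livestock
#' sector — region-specific where the region map and footprint table
#' provide one, otherwise the `"GLOBAL"` row (logged). Countries with
#' neither a regional nor a global footprint for a sector are flagged
#' ineligible for the land stage rather than dropped.
#'
#' Harmonization is idempotent: passing a `country_panel` back in
#' returns an identical panel.
#'
#' @param tables Named list of tibbles as returned by [read_table()] or
#'   [generate_panel()]`$inputs`: any of `nutrient_supply`,
#'   `fao_balance`, `population`, `food_security_index`, `footprints`,
#'   `characterization_factors`, `sector_protein`, `region_map`.
#'   A `country_panel` may be passed instead.
#' @param alias_extra Optional extra alias rows (see [resolve_iso3()]).
#' @param reference_year Population reference year (default 2019).
#' @return A `country_panel` object: a list of harmonized component
#'   tibbles plus a `log` of clamps/fallbacks and a `quarantine` table
#'   of unresolvable rows.
#' @export
harmonize_countries <- function(tables, alias_extra = NULL,
                                reference_year = 2019) {
  if (inherits(tables, "country_panel")) {
    tables <- tables$tables
  }
  stopifnot(is.list(tables))
  quarantine <- tibble(table = character(), country = character(),
                       reason = character())
  log <- tibble(stage = character(), country = character(),
                detail = character())

  keyed <- c("nutrient_supply", "fao_balance", "population",
             "food_security_index", "characterization_factors",
             "sector_protein", "region_map")
  for (nm in keyed) {
    if (!is.null(tables[[nm]])) {
      res <- .wm_resolve_key(tables[[nm]], nm, alias_extra, quarantine)
      tables[[nm]] <- res$tab
      quarantine <- res$quarantine
    }
  }

  nutrient <- tables$nutrient_supply
  if (!is.null(nutrient) && nrow(nutrient) > 0) {
    over_animal <- nutrient$animal_protein > nutrient$P_current
    if (any(over_animal)) {
      log <- bind_rows(log, tibble(
        stage = "clamp", country = nutrient$country[over_animal],
        detail = "animal_protein clamped to P_current"))
      nutrient$animal_protein[over_animal] <-
        nutrient$P_current[over_animal]
    }
    over_wild <- nutrient$W_PPPD > nutrient$animal_protein
    if (any(over_wild)) {
      log <- bind_rows(log, tibble(
        stage = "clamp", country = nutrient$country[over_wild],
        detail = "W_PPPD clamped to animal_protein"))
      nutrient$W_PPPD[over_wild] <- nutrient$animal_protein[over_wild]
    }
    nutrient <- distinct(nutrient, .data$country, .keep_all = TRUE)
  }

  population <- tables$population
  if (!is.null(population) && nrow(population) > 0) {
    population <- population |>
      mutate(.pref = if_else(.data$year == reference_year, 1L, 0L)) |>
      group_by(.data$country) |>
      arrange(dplyr::desc(.data$.pref), dplyr::desc(.data$year)) |>
      dplyr::slice(1) |>
      ungroup() |>
      select(-".pref")
  }

  index <- tables$food_security_index
  if (!is.null(index) && nrow(index) > 0) {
    index <- distinct(index, .data$country, .keep_all = TRUE)
  }

  countries <- sort(unique(c(
    if (!is.null(nutrient)) nutrient$country,
    if (!is.null(tables$fao_balance)) tables$fao_balance$country,
    if (!is.null(population)) population$country,
    if (!is.null(index)) index$country,
    if (!is.null(tables$characterization_factors))
      tables$characterization_factors$country,
    if (!is.null(tables$sector_protein)) tables$sector_protein$country
  )))

  # Resolve a footprint row for every country x sector.
  fps <- tables$footprints
  region_map <- tables$region_map
  resolved <- NULL
  if (!is.null(fps) && nrow(fps) > 0) {
    grid <- tidyr::expand_grid(country = countries, sector = WM_SECTORS)
    if (!is.null(region_map) && nrow(region_map) > 0) {
      grid <- left_join(grid, region_map[, c("country", "region")],
                        by = "country")
    } else {
      grid$region <- NA_character_
    }
    regional <- rename(fps, fp_region = "region")
    resolved <- grid |>
      left_join(regional, by = c(region = "fp_region", sector = "sector")) |>
      left_join(filter(fps, .data$region == "GLOBAL") |>
                  select(-"region") |>
                  rename(L_past_glob = "L_past_m2yr_per_kg",
                         L_crop_glob = "L_crop_m2yr_per_kg",
                         pc_glob = "protein_content"),
                by = "sector")
    fellback <- is.na(resolved$L_past_m2yr_per_kg) &
      !is.na(resolved$L_past_glob)
    if (any(fellback)) {
      log <- bind_rows(log, tibble(
        stage = "footprint_fallback",
        country = resolved$country[fellback],
        detail = paste0("sector ", resolved$sector[fellback],
                        ": GLOBAL footprint used")))
    }
    resolved <- resolved |>
      mutate(
        global_fallback = fellback,
        L_past_m2yr_per_kg = if_else(fellback, .data$L_past_glob,
                                     .data$L_past_m2yr_per_kg),
        L_crop_m2yr_per_kg = if_else(fellback, .data$L_crop_glob,
                                     .data$L_crop_m2yr_per_kg),
        protein_content = if_else(fellback, .data$pc_glob,
                                  .data$protein_content)
      ) |>
      select("country", "sector", "L_past_m2yr_per_kg",
             "L_crop_m2yr_per_kg", "protein_content", "global_fallback")
  }

  tables$nutrient_supply <- nutrient
  tables$population <- population
  tables$food_security_index <- index

  structure(list(
    countries = countries,
    nutrient = nutrient,
    balance = tables$fao_balance,
    population = population,
    index = index,
    sector_protein = tables$sector_protein,
    footprints = resolved,
    cfs = tables$characterization_factors,
    region_map = region_map,
    reference_year = reference_year,
    tables = tables,
    log = log,
    quarantine = quarantine
  ), class = "country_panel")
}

#' @export
print.country_panel <- function(x, ...) {
  cat("<country_panel> ", length(x$countries), " countries\n", sep = "")
  cat("  nutrient records:  ",
      if (is.null(x$nutrient)) 0 else nrow(x$nutrient), "\n", sep = "")
  cat("  balance records:   ",
      if (is.null(x$balance)) 0 else nrow(x$balance), "\n", sep = "")
  cat("  index records:     ",
      if (is.null(x$index)) 0 else nrow(x$index), "\n", sep = "")
  cat("  log entries:       ", nrow(x$log),
      "; quarantined rows: ", nrow(x$quarantine), "\n", sep = "")
  invisible(x)
}
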
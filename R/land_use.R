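#' Replacement shares across livestock sectors
#'
#' Wild-meat protein is replaced by the four livestock sectors (beef,
#' sheep/goat, pork, poultry) in proportion to their current share of
#' the country's meat-protein consumption. If a country reports no
#' meat protein in any sector, equal shares are assigned with a
#' warning.
#'
#' @param sector_protein Named numeric vector of current meat-protein
#'   supply by sector, g/person/day (names from
#'   `c("beef","sheep_goat","pork","poultry")`; missing sectors count
#'   as 0), or a tibble with columns `sector, protein_gppd`.
#' @return Named numeric vector of shares over the four sectors,
#'   summing to 1.
#' @examples
#' sector_shares(c(poultry = 20, beef = 30, pork = 50))
#' @export
sector_shares <- function(sector_protein) {
  if (is.data.frame(sector_protein)) {
    sector_protein <- setNames(sector_protein$protein_gppd,
                               sector_protein$sector)
  }
  if (is.null(names(sector_protein)) ||
      !all(names(sector_protein) %in% WM_SECTORS)) {
    abort(paste0("sector names must be among: ",
                 paste(WM_SECTORS, collapse = ", ")),
          class = "wm_usage_error")
  }
  if (any(sector_protein < 0)) {
    abort("sector protein must be >= 0", class = "wm_domain_error")
  }
  full <- setNames(rep(0, length(WM_SECTORS)), WM_SECTORS)
  full[names(sector_protein)] <- sector_protein
  tot <- sum(full)
  if (tot == 0) {
    warn("no meat-sector protein reported; using equal shares")
    return(setNames(rep(1 / length(WM_SECTORS), length(WM_SECTORS)),
                    WM_SECTORS))
  }
  full / tot
}

#' Land required to replace wild-meat protein for one country
#'
#' Pasture and feed-cropland area needed to produce `W` kg of
#' replacement livestock protein, share-weighted across sectors:
#' for sector i, `pasture_i = share_i x W x L_past_i` and
#' `crop_i = share_i x W x L_crop_i`, computed in m2 and reported in
#' km2.
#'
#' @param W Wild-meat protein to replace, kg/year (`>= 0`).
#' @param shares Named shares from [sector_shares()].
#' @param footprints Tibble with columns `sector, L_past_m2yr_per_kg,
#'   L_crop_m2yr_per_kg` covering every sector with share > 0.
#' @return Tibble with one row per sector: `sector, share,
#'   pasture_km2, cropland_km2`; attributes `L_pasture_km2`,
#'   `L_crop_km2`, `L_total_km2` hold the totals.
#' @examples
#' fp <- tibble::tibble(sector = "beef", L_past_m2yr_per_kg = 50,
#'                      L_crop_m2yr_per_kg = 10)
#' land_demand(1000, c(beef = 1), fp) # 0.05 + 0.01 = 0.06 km2
#' @export
land_demand <- function(W, shares, footprints) {
  if (length(W) != 1 || W < 0) {
    abort("W must be a single value >= 0", class = "wm_domain_error")
  }
  if (abs(sum(shares) - 1) > 1e-9 || any(shares < 0)) {
    abort("shares must be >= 0 and sum to 1", class = "wm_domain_error")
  }
  active <- names(shares)[shares > 0]
  idx <- match(active, footprints$sector)
  missing <- active[is.na(idx) |
                      is.na(footprints$L_past_m2yr_per_kg[idx]) |
                      is.na(footprints$L_crop_m2yr_per_kg[idx])]
  if (length(missing) > 0) {
    abort(paste0("no footprint for sector(s) with share > 0: ",
                 paste(missing, collapse = ", ")),
          class = "wm_data_error")
  }
  out <- tibble(sector = names(shares), share = unname(shares)) |>
    left_join(footprints[, c("sector", "L_past_m2yr_per_kg",
                             "L_crop_m2yr_per_kg")],
              by = "sector") |>
    mutate(
      pasture_km2 = .data$share * W *
        dplyr::coalesce(.data$L_past_m2yr_per_kg, 0) / 1e6,
      cropland_km2 = .data$share * W *
        dplyr::coalesce(.data$L_crop_m2yr_per_kg, 0) / 1e6
    ) |>
    select("sector", "share", "pasture_km2", "cropland_km2")
  attr(out, "L_pasture_km2") <- sum(out$pasture_km2)
  attr(out, "L_crop_km2") <- sum(out$cropland_km2)
  attr(out, "L_total_km2") <- sum(out$pasture_km2) +
    sum(out$cropland_km2)
  out
}

#' Land demand for every country in a panel
#'
#' Applies [sector_shares()] and [land_demand()] per country over the
#' merged consumption estimates (only countries with non-zero
#' consumption are eligible for this stage).
#'
#' @param panel A `country_panel`.
#' @param consumption Output of [estimate_consumption()], or any tibble
#'   with `country` and `W_kg_protein_yr` columns.
#' @return List of class `land_demand_table`:
#'   `by_sector` (tibble `country, sector, share, pasture_km2,
#'   cropland_km2`) and `totals` (tibble `country, L_pasture_km2,
#'   L_crop_km2, L_total_km2`).
#' @export
land_demand_all <- function(panel, consumption) {
  stopifnot(inherits(panel, "country_panel"))
  if (is.null(panel$footprints)) {
    abort("panel has no footprint table", class = "wm_data_error")
  }
  sp <- panel$sector_protein
  by_sector <- vector("list", nrow(consumption))
  for (i in seq_len(nrow(consumption))) {
    cty <- consumption$country[i]
    prot <- if (!is.null(sp)) sp[sp$country == cty, ] else sp[0, ]
    shares <- if (is.null(prot) || nrow(prot) == 0) {
      warn(paste0("no meat-sector data for ", cty,
                  "; using equal shares"))
      setNames(rep(0.25, 4), WM_SECTORS)
    } else {
      sector_shares(prot)
    }
    fp <- panel$footprints[panel$footprints$country == cty, ]
    ld <- land_demand(consumption$W_kg_protein_yr[i], shares, fp)
    ld$country <- cty
    by_sector[[i]] <- ld
  }
  by_sector <- bind_rows(by_sector) |>
    select("country", "sector", "share", "pasture_km2", "cropland_km2")
  totals <- by_sector |>
    group_by(.data$country) |>
    summarise(L_pasture_km2 = sum(.data$pasture_km2),
              L_crop_km2 = sum(.data$cropland_km2),
              .groups = "drop") |>
    mutate(L_total_km2 = .data$L_pasture_km2 + .data$L_crop_km2) |>
    arrange(.data$country)
  structure(list(by_sector = by_sector, totals = totals),
            class = "land_demand_table")
}
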
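#' Species committed to extinction by replacement land use
#'
#' Converts land demand into species "destined for extinction" using
#' country-specific characterization factors derived from countryside
#' species-area relationships: a one-off transformation impact per km2
#' converted (`C_past`, `C_crop`) plus an ongoing occupation impact per
#' km2 per year (`O_past`, `O_crop`) accumulated over a horizon:
#'
#' `B_loss = L_pasture x (C_past + horizon x O_past) +
#'           L_crop x (C_crop + horizon x O_crop)`
#'
#' `eq4_as_printed = TRUE` reproduces a published variant in which the
#' cropland occupation term uses the pasture occupation factor; the
#' default follows the described method, where each land type carries
#' its own occupation factor.
#'
#' @param land Tibble with columns `country, L_pasture_km2,
#'   L_crop_km2` (e.g. [land_demand_all()]`$totals`).
#' @param cfs Tibble with columns `country, C_past, C_crop, O_past,
#'   O_crop` (species/km2 and species/(km2 yr)).
#' @param horizon Years of continued occupation (default 10, `>= 0`).
#'   At `horizon = 0` only the transformation term remains.
#' @param eq4_as_printed Use `O_past` in the cropland term (default
#'   `FALSE`).
#' @return Tibble with columns `country, loss_pasture, loss_crop,
#'   one_off, occupation, B_loss, horizon` (species).
#' @examples
#' land <- tibble::tibble(country = "XAA", L_pasture_km2 = 0.05,
#'                        L_crop_km2 = 0.01)
#' cfs <- tibble::tibble(country = "XAA", C_past = 1e-3, C_crop = 2e-3,
#'                       O_past = 1e-4, O_crop = 2e-4)
#' biodiversity_loss(land, cfs) # B_loss = 1.4e-4 species
#' @export
biodiversity_loss <- function(land, cfs, horizon = 10,
                              eq4_as_printed = FALSE) {
  if (length(horizon) != 1 || horizon < 0) {
    abort("horizon must be a single value >= 0",
          class = "wm_domain_error")
  }
  land <- as_tibble(land)
  cfs <- as_tibble(cfs)
  missing <- setdiff(land$country, cfs$country)
  if (length(missing) > 0) {
    abort(paste0("no characterization factors for country(ies): ",
                 paste(missing, collapse = ", ")),
          class = "wm_keying_error")
  }
  joined <- inner_join(
    land[, c("country", "L_pasture_km2", "L_crop_km2")],
    cfs[, c("country", "C_past", "C_crop", "O_past", "O_crop")],
    by = "country")
  o_crop_eff <- if (eq4_as_printed) joined$O_past else joined$O_crop
  joined |>
    mutate(
      loss_pasture = .data$L_pasture_km2 *
        (.data$C_past + horizon * .data$O_past),
      loss_crop = .data$L_crop_km2 * (.data$C_crop + horizon * o_crop_eff),
      one_off = .data$L_pasture_km2 * .data$C_past +
        .data$L_crop_km2 * .data$C_crop,
      occupation = horizon * (.data$L_pasture_km2 * .data$O_past +
                                .data$L_crop_km2 * o_crop_eff),
      B_loss = .data$loss_pasture + .data$loss_crop,
      horizon = horizon
    ) |>
    select("country", "loss_pasture", "loss_crop", "one_off",
           "occupation", "B_loss", "horizon") |>
    arrange(.data$country)
}
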
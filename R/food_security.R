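#' Worst-case protein deficit after wild-meat removal
#'
#' Hypothetical per-capita protein supply if wild meat is removed with
#' no alternatives: `P_removal = P_current - W_PPPD`.
#'
#' @param p_current Total protein supply from all foods, g/person/day.
#' @param w_pppd Wild-meat protein supply, g/person/day
#'   (`0 <= w_pppd <= p_current`; harmonization clamps upstream).
#' @return `P_removal`, g/person/day.
#' @examples
#' protein_deficit(60, 10) # 50
#' @export
protein_deficit <- function(p_current, w_pppd) {
  if (any(w_pppd < 0)) {
    abort("w_pppd must be >= 0", class = "wm_domain_error")
  }
  if (any(w_pppd > p_current)) {
    abort("w_pppd exceeds p_current; harmonize inputs first",
          class = "wm_domain_error")
  }
  p_current - w_pppd
}

#' Wild-meat share of animal protein
#'
#' @param w_pppd Wild-meat protein, g/person/day.
#' @param animal_protein Total animal protein, g/person/day
#'   (`>= w_pppd`).
#' @return Fraction in `[0, 1]`. A country with no animal protein at
#'   all returns 0 with a warning.
#' @examples
#' wild_share(15, 30) # 0.5
#' @export
wild_share <- function(w_pppd, animal_protein) {
  if (any(w_pppd < 0) || any(animal_protein < w_pppd)) {
    abort("need 0 <= w_pppd <= animal_protein",
          class = "wm_domain_error")
  }
  zero <- animal_protein == 0
  if (any(zero)) {
    warn("animal_protein is 0; wild-meat share reported as 0")
  }
  if_else(zero, 0, w_pppd / animal_protein)
}

#' Flag protein supplies below the WHO recommended minimum
#'
#' @param p_removal Post-removal protein supply, g/person/day.
#' @param who_threshold WHO recommended minimum protein intake,
#'   g/person/day (`> 0`).
#' @return `TRUE` iff `p_removal < who_threshold` (strict: a country
#'   exactly at the threshold is not flagged).
#' @export
flag_below_who <- function(p_removal, who_threshold) {
  if (any(who_threshold <= 0)) {
    abort("who_threshold must be > 0", class = "wm_domain_error")
  }
  p_removal < who_threshold
}

#' Classify food-insecurity risk
#'
#' A country is `HIGH_RISK` when it relies on wild meat for more than
#' 5% of its animal protein (strict) and sits in the bottom half of the
#' food-security ranking (strict: `rank > n_ranked / 2`, larger rank =
#' more food-insecure; rank 57 of 113 qualifies). Countries without a
#' rank are `UNRANKED`, never silently dropped.
#'
#' @param share Wild-meat share of animal protein, fraction.
#' @param rank Food-security rank (1 = most secure) or `NA`.
#' @param n_ranked Total countries ranked.
#' @param share_threshold Share cutoff (default 0.05).
#' @return Character vector in
#'   `{"HIGH_RISK", "NOT_HIGH_RISK", "UNRANKED"}`.
#' @examples
#' classify_risk(0.73, 84, 113) # HIGH_RISK
#' @export
classify_risk <- function(share, rank, n_ranked,
                          share_threshold = 0.05) {
  if (any(share < 0 | share > 1)) {
    abort("share must be in [0, 1]", class = "wm_domain_error")
  }
  ok <- is.na(rank) | (rank >= 1 & rank <= n_ranked)
  if (!all(ok)) {
    abort("rank must satisfy 1 <= rank <= n_ranked",
          class = "wm_domain_error")
  }
  case_when(
    is.na(rank) ~ "UNRANKED",
    share > share_threshold & rank > n_ranked / 2 ~ "HIGH_RISK",
    TRUE ~ "NOT_HIGH_RISK"
  )
}

#' Food-insecurity assessment for a panel
#'
#' Combines the consumption estimates with the panel's nutrient and
#' food-security-index records: post-removal protein supply, wild-meat
#' share of animal protein, the WHO-minimum flag, and the risk
#' category. Countries lacking a nutrient-supply record cannot enter
#' this stage and are listed in the `"skipped"` attribute.
#'
#' @param panel A `country_panel`.
#' @param consumption Output of [estimate_consumption()].
#' @param who_threshold WHO recommended minimum protein intake,
#'   g/person/day.
#' @return Tibble with columns `country, P_current, W_PPPD_g,
#'   P_removal, wild_share, below_who, risk_category, rank, n_ranked`.
#' @export
assess_food_security <- function(panel, consumption,
                                 who_threshold = 50) {
  stopifnot(inherits(panel, "country_panel"))
  if (is.null(panel$nutrient) || nrow(panel$nutrient) == 0) {
    abort("panel has no nutrient-supply records",
          class = "wm_data_error")
  }
  joined <- consumption |>
    inner_join(select(panel$nutrient, "country", "P_current",
                      "animal_protein"),
               by = "country")
  skipped <- setdiff(consumption$country, joined$country)
  # Balance-sheet-derived W_PPPD can exceed the nutrient-supply totals
  # for inconsistent sources; bound it so the deficit stays meaningful.
  over <- joined$W_PPPD_g > joined$animal_protein
  if (any(over)) {
    warn(paste0("back-derived W_PPPD exceeds animal protein for ",
                paste(joined$country[over], collapse = ", "),
                "; clamped"))
    joined$W_PPPD_g[over] <- joined$animal_protein[over]
  }
  idx <- if (!is.null(panel$index)) panel$index else
    tibble(country = character(), rank = integer(),
           n_ranked = integer())
  out <- joined |>
    mutate(
      P_removal = protein_deficit(.data$P_current, .data$W_PPPD_g),
      wild_share = wild_share(.data$W_PPPD_g, .data$animal_protein),
      below_who = flag_below_who(.data$P_removal, who_threshold)
    ) |>
    left_join(select(idx, "country", "rank", "n_ranked"),
              by = "country") |>
    mutate(risk_category = classify_risk(.data$wild_share, .data$rank,
                                         .data$n_ranked)) |>
    select("country", "P_current", "W_PPPD_g", "P_removal",
           "wild_share", "below_who", "risk_category", "rank",
           "n_ranked") |>
    arrange(.data$country)
  attr(out, "who_threshold") <- who_threshold
  attr(out, "skipped") <- sort(skipped)
  out
}
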
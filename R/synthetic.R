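#' Configuration for the synthetic country-panel generator
#'
#' Defines the cross-country distributions the generator draws from.
#' Ranges are uniform `(lo, hi)`; sector shares come from a
#' Gamma-normalised simplex sampler (a flat Dirichlet). Defaults are
#' chosen once to bracket the range observed in national
#' nutrient-supply data (total protein supplies of roughly 40-110
#' g/person/day; wild-meat reliance up to about three quarters of
#' animal protein in the most dependent countries).
#'
#' @param n_countries Number of synthetic countries (`>= 1`).
#' @param seed Integer RNG seed.
#' @param protein_total_range Total protein supply, g/person/day.
#' @param animal_share_range Animal fraction of total protein, `[0,1]`.
#' @param wild_share_range Wild-meat fraction of animal protein,
#'   `[0,1]`.
#' @param population_range Persons.
#' @param n_sectors Number of livestock sectors; must be 4 (beef,
#'   sheep/goat, pork, poultry — the replacement set).
#' @param footprint_ranges Per-sector list with `pasture` and
#'   `cropland` ranges, m2 yr per kg protein.
#' @param cf_ranges List with `transformation` (species/km2) and
#'   `occupation` (species/(km2 yr)) ranges.
#' @param fao_fraction Fraction of countries reported only via the
#'   balance-sheet path (their nutrient-supply game-meat entry is
#'   zeroed and an equivalent balance-sheet record inserted).
#' @param missing_gfsi_fraction Fraction of countries without a
#'   food-security rank.
#' @param missing_region_fraction Fraction of countries assigned a
#'   region absent from the footprint table, exercising the GLOBAL
#'   fallback.
#' @param game_protein_content kg protein per kg live weight used to
#'   build (and later read back) balance-sheet records.
#' @param underreporting_factor Optional multiplier in `(0, 1]`
#'   applied to reported wild-meat quantities; 1 (the default) means
#'   sources report fully.
#' @param who_threshold,horizon Passed to the ground-truth oracle.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(
    n_countries,
    seed = 1L,
    protein_total_range = c(40, 110),
    animal_share_range = c(0.2, 0.7),
    wild_share_range = c(0, 0.75),
    population_range = c(5e5, 2e8),
    n_sectors = 4L,
    footprint_ranges = list(
      beef = list(pasture = c(600, 2500), cropland = c(100, 400)),
      sheep_goat = list(pasture = c(500, 2000), cropland = c(50, 250)),
      pork = list(pasture = c(0, 50), cropland = c(350, 700)),
      poultry = list(pasture = c(0, 20), cropland = c(250, 550))
    ),
    cf_ranges = list(transformation = c(1e-5, 5e-3),
                     occupation = c(1e-6, 5e-4)),
    fao_fraction = 0.2,
    missing_gfsi_fraction = 0.15,
    missing_region_fraction = 0.1,
    game_protein_content = 0.15,
    underreporting_factor = 1,
    who_threshold = 50,
    horizon = 10) {
  bad <- function(field, why) {
    abort(paste0("invalid config field '", field, "': ", why),
          class = "wm_config_error")
  }
  if (!is.numeric(n_countries) || length(n_countries) != 1 ||
      is.na(n_countries) || n_countries < 1) {
    bad("n_countries", "must be a positive integer")
  }
  if (n_countries > 26 * 26) bad("n_countries", "at most 676 supported")
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    bad("seed", "must be a single integer")
  }
  chk_range <- function(x, field, lo_min = 0, hi_max = Inf) {
    if (!is.numeric(x) || length(x) != 2 || any(is.na(x)) ||
        x[1] > x[2] || x[1] < lo_min || x[2] > hi_max) {
      bad(field, paste0("must be a (lo, hi) range with lo <= hi in [",
                        lo_min, ", ", hi_max, "]"))
    }
  }
  chk_range(protein_total_range, "protein_total_range")
  chk_range(animal_share_range, "animal_share_range", 0, 1)
  chk_range(wild_share_range, "wild_share_range", 0, 1)
  chk_range(population_range, "population_range")
  if (population_range[1] <= 0) {
    bad("population_range", "populations must be > 0")
  }
  if (!identical(as.integer(n_sectors), 4L)) {
    bad("n_sectors", "only the 4-sector replacement set is supported")
  }
  if (!setequal(names(footprint_ranges), WM_SECTORS)) {
    bad("footprint_ranges",
        paste0("must name sectors ", paste(WM_SECTORS, collapse = ", ")))
  }
  for (s in WM_SECTORS) {
    chk_range(footprint_ranges[[s]]$pasture,
              paste0("footprint_ranges$", s, "$pasture"))
    chk_range(footprint_ranges[[s]]$cropland,
              paste0("footprint_ranges$", s, "$cropland"))
  }
  chk_range(cf_ranges$transformation, "cf_ranges$transformation")
  chk_range(cf_ranges$occupation, "cf_ranges$occupation")
  for (nm in c("fao_fraction", "missing_gfsi_fraction",
               "missing_region_fraction")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      bad(nm, "must be a fraction in [0, 1]")
    }
  }
  if (!is.numeric(game_protein_content) ||
      length(game_protein_content) != 1 ||
      game_protein_content <= 0 || game_protein_content >= 1) {
    bad("game_protein_content", "must be in (0, 1)")
  }
  if (!is.numeric(underreporting_factor) ||
      length(underreporting_factor) != 1 ||
      underreporting_factor <= 0 || underreporting_factor > 1) {
    bad("underreporting_factor", "must be in (0, 1]")
  }
  if (!is.numeric(who_threshold) || length(who_threshold) != 1 ||
      who_threshold <= 0) {
    bad("who_threshold", "must be > 0")
  }
  if (!is.numeric(horizon) || length(horizon) != 1 || horizon < 0) {
    bad("horizon", "must be >= 0")
  }
  structure(list(
    n_countries = as.integer(n_countries), seed = as.integer(seed),
    protein_total_range = protein_total_range,
    animal_share_range = animal_share_range,
    wild_share_range = wild_share_range,
    population_range = population_range,
    n_sectors = 4L,
    footprint_ranges = footprint_ranges,
    cf_ranges = cf_ranges,
    fao_fraction = fao_fraction,
    missing_gfsi_fraction = missing_gfsi_fraction,
    missing_region_fraction = missing_region_fraction,
    game_protein_content = game_protein_content,
    underreporting_factor = underreporting_factor,
    who_threshold = who_threshold,
    horizon = horizon
  ), class = "synthetic_config")
}

.wm_synth_codes <- function(n) {
  i <- seq_len(n) - 1L
  paste0("X", LETTERS[i %/% 26L + 1L], LETTERS[i %% 26L + 1L])
}

.wm_synth_regions <- c("RAF", "RAM", "RAS")

#' Generate a seeded synthetic country panel with ground truth
#'
#' Draws `n_countries` synthetic countries (ISO3-like codes in the
#' reserved `"X.."` namespace) with the statistical structure the
#' analysis assumes — wild-meat protein is a share of animal protein,
#' which is a share of total protein; sector shares live on the
#' simplex — then computes exact per-country ground truth with the
#' independent scalar oracle ([oracle_outputs()]). A `fao_fraction` of
#' countries have their nutrient-supply game-meat entry removed and an
#' equivalent balance-sheet record inserted, exercising the
#' balance-sheet estimation path end to end.
#'
#' The same config (including seed) always reproduces the identical
#' panel and truth.
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_panel` list: `config`, `inputs` (named list of
#'   input tables in the documented CSV schemas, see [wm_schemas()]),
#'   and `truth` (the oracle's per-country outputs and totals).
#' @export
generate_panel <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    abort("config must be built with synthetic_config()",
          class = "wm_config_error")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  n <- config$n_countries
  country <- .wm_synth_codes(n)

  p_total <- runif(n, config$protein_total_range[1],
                   config$protein_total_range[2])
  animal <- p_total * runif(n, config$animal_share_range[1],
                            config$animal_share_range[2])
  wild_true <- animal * runif(n, config$wild_share_range[1],
                              config$wild_share_range[2])
  population <- round(runif(n, config$population_range[1],
                            config$population_range[2]))

  meat_total <- (animal - wild_true) * runif(n, 0.3, 0.9)
  share_mat <- matrix(rgamma(n * 4L, shape = 1), nrow = n)
  share_mat <- share_mat / rowSums(share_mat)
  colnames(share_mat) <- WM_SECTORS

  region <- sample(.wm_synth_regions, n, replace = TRUE)
  region[runif(n) < config$missing_region_fraction] <- "XUN"

  fao_path <- runif(n) < config$fao_fraction
  reported_wild <- wild_true * config$underreporting_factor

  nutrient_supply <- tibble(
    country = country, year = 2011L,
    P_current = p_total, animal_protein = animal,
    W_PPPD = if_else(fao_path, 0, reported_wild)
  )

  fao_idx <- which(fao_path)
  w_annual <- reported_wild[fao_idx] * population[fao_idx] *
    WM_DAYS_PER_YEAR / 1000
  live <- w_annual / config$game_protein_content
  imports <- runif(length(fao_idx), 0, 0.5) * live
  exports <- runif(length(fao_idx), 0, 1) * imports
  fao_balance <- tibble(
    country = country[fao_idx],
    production_kg = live - imports + exports,
    imports_kg = imports, exports_kg = exports
  )

  population_tab <- tibble(country = country, year = 2019L,
                           population = population)

  ranked <- runif(n) >= config$missing_gfsi_fraction
  n_ranked <- sum(ranked)
  food_security_index <- tibble(
    country = country[ranked],
    rank = if (n_ranked > 0) sample.int(n_ranked) else integer(),
    n_ranked = n_ranked
  )

  pc_sector <- setNames(runif(4L, 0.1, 0.3), WM_SECTORS)
  fp_regions <- c(.wm_synth_regions, "GLOBAL")
  fp_rows <- list()
  for (reg in fp_regions) {
    for (s in WM_SECTORS) {
      rng <- config$footprint_ranges[[s]]
      fp_rows[[paste(reg, s)]] <- tibble(
        region = reg, sector = s,
        L_past_m2yr_per_kg = runif(1, rng$pasture[1], rng$pasture[2]),
        L_crop_m2yr_per_kg = runif(1, rng$cropland[1], rng$cropland[2]),
        protein_content = pc_sector[[s]]
      )
    }
  }
  footprints <- bind_rows(fp_rows)

  tr <- config$cf_ranges$transformation
  oc <- config$cf_ranges$occupation
  characterization_factors <- tibble(
    country = country,
    C_past = runif(n, tr[1], tr[2]), C_crop = runif(n, tr[1], tr[2]),
    O_past = runif(n, oc[1], oc[2]), O_crop = runif(n, oc[1], oc[2])
  )

  sector_protein <- tibble(
    country = rep(country, each = 4L),
    sector = rep(WM_SECTORS, times = n),
    protein_gppd = as.vector(t(share_mat * meat_total))
  )

  region_map <- tibble(country = country, region = region)

  inputs <- list(
    nutrient_supply = nutrient_supply,
    fao_balance = fao_balance,
    population = population_tab,
    food_security_index = food_security_index,
    footprints = footprints,
    characterization_factors = characterization_factors,
    sector_protein = sector_protein,
    region_map = region_map
  )

  truth <- oracle_outputs(
    inputs, horizon = config$horizon,
    who_threshold = config$who_threshold,
    game_protein_content = config$game_protein_content)

  structure(list(config = config, inputs = inputs, truth = truth),
            class = "synthetic_panel")
}

#' Independent scalar oracle for the full pipeline
#'
#' Recomputes every pipeline output — consumption, food-security
#' assessment, land demand, biodiversity loss, global totals — as a
#' deliberately naive restatement of the model arithmetic: plain `for`
#' loops over one country at a time, no vectorisation, no shared code
#' with the pipeline. Used only as ground truth in tests and in the
#' generator.
#'
#' @param inputs Named list of input tables (schemas as in
#'   [wm_schemas()]).
#' @param horizon Occupation horizon, years.
#' @param who_threshold WHO minimum protein intake, g/person/day.
#' @param game_protein_content kg protein per kg live weight for the
#'   balance-sheet path.
#' @return List of tibbles `consumption`, `food_security`,
#'   `land_totals`, `land_by_sector`, `biodiversity`, a one-row
#'   `totals` tibble, and the `excluded` zero-consumption countries.
#' @export
oracle_outputs <- function(inputs, horizon = 10, who_threshold = 50,
                           game_protein_content = 0.15) {
  nut <- inputs$nutrient_supply
  bal <- inputs$fao_balance
  pop <- inputs$population
  idx <- inputs$food_security_index
  fps <- inputs$footprints
  cfs <- inputs$characterization_factors
  sp <- inputs$sector_protein
  rmap <- inputs$region_map

  countries <- sort(unique(c(nut$country, bal$country)))
  cons_rows <- list()
  fs_rows <- list()
  land_tot_rows <- list()
  land_sec_rows <- list()
  bio_rows <- list()
  excluded <- character()

  for (cty in countries) {
    p_row <- pop[pop$country == cty, ]
    if (nrow(p_row) == 0) next
    p <- p_row$population[1]

    n_row <- nut[nut$country == cty, ]
    b_row <- bal[bal$country == cty, ]

    w <- 0
    w_pppd <- 0
    live <- NA_real_
    src <- NA_character_
    if (nrow(n_row) == 1 && n_row$W_PPPD > 0) {
      w_pppd <- n_row$W_PPPD
      w <- w_pppd * p * 365.25 / 1000
      src <- "GENUS"
    } else if (nrow(b_row) == 1) {
      apparent <- b_row$production_kg + b_row$imports_kg -
        b_row$exports_kg
      if (apparent < 0) apparent <- 0
      live <- apparent
      w <- apparent * game_protein_content
      w_pppd <- w / p / 365.25 * 1000
      src <- "FAO"
    }
    if (w <= 0) {
      excluded <- c(excluded, cty)
      next
    }
    cons_rows[[cty]] <- tibble(
      country = cty, W_kg_protein_yr = w, W_PPPD_g = w_pppd,
      live_weight_kg = live, source = src)

    # --- food security (Eq. 2 plus flags) ---
    if (nrow(n_row) == 1) {
      p_cur <- n_row$P_current
      an <- n_row$animal_protein
      w_fs <- if (w_pppd > an) an else w_pppd
      p_rem <- p_cur - w_fs
      share <- if (an == 0) 0 else w_fs / an
      below <- p_rem < who_threshold
      i_row <- idx[idx$country == cty, ]
      if (nrow(i_row) == 1) {
        rnk <- i_row$rank
        n_r <- i_row$n_ranked
        risk <- if (share > 0.05 && rnk > n_r / 2) "HIGH_RISK"
        else "NOT_HIGH_RISK"
      } else {
        rnk <- NA_integer_
        n_r <- NA_integer_
        risk <- "UNRANKED"
      }
      fs_rows[[cty]] <- tibble(
        country = cty, P_current = p_cur, W_PPPD_g = w_fs,
        P_removal = p_rem, wild_share = share, below_who = below,
        risk_category = risk, rank = rnk, n_ranked = n_r)
    }

    # --- land demand (Eq. 3) ---
    sp_rows <- sp[sp$country == cty, ]
    shares <- setNames(rep(0, 4), WM_SECTORS)
    tot_meat <- 0
    for (s in WM_SECTORS) {
      v <- sp_rows$protein_gppd[sp_rows$sector == s]
      if (length(v) == 1) {
        shares[[s]] <- v
        tot_meat <- tot_meat + v
      }
    }
    if (tot_meat > 0) {
      for (s in WM_SECTORS) shares[[s]] <- shares[[s]] / tot_meat
    } else {
      for (s in WM_SECTORS) shares[[s]] <- 0.25
    }
    reg <- rmap$region[rmap$country == cty]
    l_past_tot <- 0
    l_crop_tot <- 0
    for (s in WM_SECTORS) {
      f_row <- if (length(reg) == 1) {
        fps[fps$sector == s & fps$region == reg, ]
      } else {
        fps[0, ]
      }
      if (nrow(f_row) == 0) {
        f_row <- fps[fps$sector == s & fps$region == "GLOBAL", ]
      }
      if (nrow(f_row) == 0) {
        abort(paste0("oracle: no footprint for ", cty, " sector ", s),
              class = "wm_data_error")
      }
      past_km2 <- shares[[s]] * w * f_row$L_past_m2yr_per_kg[1] / 1e6
      crop_km2 <- shares[[s]] * w * f_row$L_crop_m2yr_per_kg[1] / 1e6
      land_sec_rows[[paste(cty, s)]] <- tibble(
        country = cty, sector = s, share = shares[[s]],
        pasture_km2 = past_km2, cropland_km2 = crop_km2)
      l_past_tot <- l_past_tot + past_km2
      l_crop_tot <- l_crop_tot + crop_km2
    }
    land_tot_rows[[cty]] <- tibble(
      country = cty, L_pasture_km2 = l_past_tot,
      L_crop_km2 = l_crop_tot,
      L_total_km2 = l_past_tot + l_crop_tot)

    # --- biodiversity (Eq. 4) ---
    cf_row <- cfs[cfs$country == cty, ]
    if (nrow(cf_row) == 0) {
      abort(paste0("oracle: no characterization factors for ", cty),
            class = "wm_data_error")
    }
    loss_past <- l_past_tot * (cf_row$C_past + horizon * cf_row$O_past)
    loss_crop <- l_crop_tot * (cf_row$C_crop + horizon * cf_row$O_crop)
    bio_rows[[cty]] <- tibble(
      country = cty, loss_pasture = loss_past, loss_crop = loss_crop,
      one_off = l_past_tot * cf_row$C_past +
        l_crop_tot * cf_row$C_crop,
      occupation = horizon * (l_past_tot * cf_row$O_past +
                                l_crop_tot * cf_row$O_crop),
      B_loss = loss_past + loss_crop, horizon = horizon)
  }

  consumption <- bind_rows(cons_rows)
  food_security <- bind_rows(fs_rows)
  land_totals <- bind_rows(land_tot_rows)
  land_by_sector <- bind_rows(land_sec_rows)
  biodiversity <- bind_rows(bio_rows)

  tot_land <- 0
  tot_past <- 0
  tot_crop <- 0
  tot_b <- 0
  n_below <- 0
  n_high <- 0
  for (i in seq_len(nrow(land_totals))) {
    tot_past <- tot_past + land_totals$L_pasture_km2[i]
    tot_crop <- tot_crop + land_totals$L_crop_km2[i]
    tot_land <- tot_land + land_totals$L_total_km2[i]
  }
  for (i in seq_len(nrow(biodiversity))) {
    tot_b <- tot_b + biodiversity$B_loss[i]
  }
  for (i in seq_len(nrow(food_security))) {
    if (food_security$below_who[i]) n_below <- n_below + 1
    if (food_security$risk_category[i] == "HIGH_RISK")
      n_high <- n_high + 1
  }
  totals <- tibble(
    n_countries = nrow(consumption),
    L_pasture_km2 = tot_past, L_crop_km2 = tot_crop,
    L_total_km2 = tot_land, B_loss = tot_b,
    n_below_who = n_below, n_high_risk = n_high)

  list(consumption = consumption, food_security = food_security,
       land_totals = land_totals, land_by_sector = land_by_sector,
       biodiversity = biodiversity, totals = totals,
       excluded = sort(excluded))
}

#' Write a synthetic panel's input tables to CSV
#'
#' Writes one `<schema>.csv` per input table under `dir`, in the
#' schemas consumed by [read_table()], so synthetic data exercises the
#' real readers.
#'
#' @param panel A `synthetic_panel` from [generate_panel()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of paths written.
#' @export
write_panel_tables <- function(panel, dir) {
  stopifnot(inherits(panel, "synthetic_panel"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (nm in names(panel$inputs)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(panel$inputs[[nm]], path)
    paths[[nm]] <- path
  }
  invisible(paths)
}

#' Read a directory of input tables
#'
#' Counterpart of [write_panel_tables()]: reads every `<schema>.csv`
#' found under `dir` with [read_table()].
#'
#' @param dir Directory containing `<schema>.csv` files.
#' @return Named list of validated tables, ready for
#'   [harmonize_countries()].
#' @export
read_panel_tables <- function(dir) {
  out <- list()
  for (nm in wm_schemas()) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (file.exists(path)) out[[nm]] <- read_table(path, nm)
  }
  out
}
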
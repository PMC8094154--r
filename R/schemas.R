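#' Input table schemas
#'
#' The pipeline consumes country-level tables in fixed CSV schemas
#' (UTF-8, header row, comma separated). Six core tables carry the
#' nutrient-supply, balance-sheet, population, food-security-index,
#' land-footprint and characterization-factor data; two auxiliary tables
#' (`sector_protein`, `region_map`) carry the per-sector meat-protein
#' supplies used for replacement weighting and the country-to-region
#' assignment used to resolve region-specific footprints.
#'
#' Columns by schema:
#' \describe{
#'   \item{nutrient_supply}{`country, year, P_current, animal_protein, W_PPPD`
#'     — per-capita protein supplies in g/person/day; `W_PPPD` is the
#'     game-meat component.}
#'   \item{fao_balance}{`country, production_kg, imports_kg, exports_kg`
#'     — game-meat live weight, kg/year.}
#'   \item{population}{`country, year, population` — persons.}
#'   \item{food_security_index}{`country, rank, n_ranked` — rank 1 is the
#'     most food-secure country; larger rank means more food-insecure.}
#'   \item{footprints}{`region, sector, L_past_m2yr_per_kg,
#'     L_crop_m2yr_per_kg, protein_content` — pasture and feed-cropland
#'     area per kg of livestock protein (m2 yr / kg); region `"GLOBAL"`
#'     is the fallback row. Sources published per 100 g protein must be
#'     multiplied by 10 before ingestion.}
#'   \item{characterization_factors}{`country, C_past, C_crop, O_past,
#'     O_crop` — species committed to extinction per km2 of habitat
#'     transformation (`C_*`) and per km2 per year of occupation
#'     (`O_*`). Sources published per m2 must be multiplied by 1e6.}
#'   \item{sector_protein}{`country, sector, protein_gppd` — current
#'     meat-protein supply by livestock sector, g/person/day.}
#'   \item{region_map}{`country, region` — footprint region assignment.}
#' }
#'
#' @return `wm_schemas()` returns the character vector of known schema
#'   names.
#' @export
wm_schemas <- function() names(.wm_schema_registry)

.wm_valid_sector <- function(x) x %in% WM_SECTORS

# Each schema: column names, per-column converter, and a row validator
# returning NA_character_ for a valid row or a reason string.
.wm_schema_registry <- list(
  nutrient_supply = list(
    cols = c(country = "c", year = "i", P_current = "d",
             animal_protein = "d", W_PPPD = "d"),
    validate = function(r) {
      if (r$P_current < 0) return("P_current must be >= 0")
      if (r$animal_protein < 0) return("animal_protein must be >= 0")
      if (r$W_PPPD < 0) return("W_PPPD must be >= 0")
      NA_character_
    }
  ),
  fao_balance = list(
    cols = c(country = "c", production_kg = "d", imports_kg = "d",
             exports_kg = "d"),
    validate = function(r) {
      if (r$production_kg < 0 || r$imports_kg < 0 || r$exports_kg < 0)
        return("balance-sheet quantities must be >= 0")
      NA_character_
    }
  ),
  population = list(
    cols = c(country = "c", year = "i", population = "d"),
    validate = function(r) {
      if (!(r$population > 0)) return("population must be > 0")
      NA_character_
    }
  ),
  food_security_index = list(
    cols = c(country = "c", rank = "i", n_ranked = "i"),
    validate = function(r) {
      if (r$rank < 1 || r$rank > r$n_ranked)
        return("rank must satisfy 1 <= rank <= n_ranked")
      NA_character_
    }
  ),
  footprints = list(
    cols = c(region = "c", sector = "c", L_past_m2yr_per_kg = "d",
             L_crop_m2yr_per_kg = "d", protein_content = "d"),
    validate = function(r) {
      if (!.wm_valid_sector(r$sector))
        return(paste0("sector must be one of ",
                      paste(WM_SECTORS, collapse = ", ")))
      if (r$L_past_m2yr_per_kg < 0 || r$L_crop_m2yr_per_kg < 0)
        return("land footprints must be >= 0")
      if (!(r$protein_content > 0 && r$protein_content < 1))
        return("protein_content must be in (0, 1)")
      NA_character_
    }
  ),
  characterization_factors = list(
    cols = c(country = "c", C_past = "d", C_crop = "d",
             O_past = "d", O_crop = "d"),
    validate = function(r) {
      if (r$C_past < 0 || r$C_crop < 0 || r$O_past < 0 || r$O_crop < 0)
        return("characterization factors must be >= 0")
      NA_character_
    }
  ),
  sector_protein = list(
    cols = c(country = "c", sector = "c", protein_gppd = "d"),
    validate = function(r) {
      if (!.wm_valid_sector(r$sector))
        return(paste0("sector must be one of ",
                      paste(WM_SECTORS, collapse = ", ")))
      if (r$protein_gppd < 0) return("protein_gppd must be >= 0")
      NA_character_
    }
  ),
  region_map = list(
    cols = c(country = "c", region = "c"),
    validate = function(r) NA_character_
  )
)

.wm_convert_col <- function(x, type) {
  switch(type,
    c = as.character(x),
    d = suppressWarnings(as.numeric(x)),
    i = suppressWarnings(as.integer(as.numeric(x)))
  )
}

#' Read and validate one input table
#'
#' Reads a CSV file against one of the documented schemas (see
#' [wm_schemas()]), validating every row against the schema's field
#' types and invariants. Invalid rows are quarantined — never silently
#' dropped — and reported with their row number and reason in the
#' `"rejected"` attribute and a warning.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Schema name, one of [wm_schemas()].
#' @return A tibble of accepted, typed records with attributes
#'   `"rejected"` (tibble of `row`, `reason`) and `"schema"`.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("country,year,population", "XAA,2019,1000000"), tf)
#' read_table(tf, "population")
#' @export
read_table <- function(path, schema) {
  if (!is.character(schema) || length(schema) != 1 ||
      !schema %in% wm_schemas()) {
    abort(paste0("unknown schema '", paste(schema, collapse = ","),
                 "'; must be one of: ",
                 paste(wm_schemas(), collapse = ", ")),
          class = "wm_usage_error")
  }
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "wm_usage_error")
  }
  spec <- .wm_schema_registry[[schema]]
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  missing <- setdiff(names(spec$cols), names(raw))
  if (length(missing) > 0) {
    abort(paste0("malformed header for schema '", schema,
                 "': missing column(s) ",
                 paste(missing, collapse = ", ")),
          class = "wm_format_error")
  }
  raw <- raw[names(spec$cols)]
  typed <- as_tibble(setNames(
    lapply(names(spec$cols),
           function(nm) .wm_convert_col(raw[[nm]], spec$cols[[nm]])),
    names(spec$cols)))
  reasons <- character(nrow(typed))
  for (i in seq_len(nrow(typed))) {
    row <- as.list(typed[i, ])
    bad <- names(spec$cols)[vapply(row, function(v) is.na(v), logical(1))]
    if (length(bad) > 0) {
      reasons[i] <- paste0("missing or non-numeric value in ",
                           paste(bad, collapse = ", "))
    } else {
      reasons[i] <- spec$validate(row)
    }
  }
  keep <- is.na(reasons)
  rejected <- tibble(row = which(!keep), reason = reasons[!keep])
  if (nrow(rejected) > 0) {
    warn(paste0(nrow(rejected), " row(s) rejected reading '", schema,
                "': ",
                paste(sprintf("row %d: %s", rejected$row,
                              rejected$reason),
                      collapse = "; ")))
  }
  out <- typed[keep, ]
  attr(out, "rejected") <- rejected
  attr(out, "schema") <- schema
  out
}
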
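#' Published range projections for 61 (sub)arctic mammals
#'
#' `load_table1_fixture()` returns the machine-readable transcription of the
#' published per-species projection table: for each of 61 mammal species,
#' its habitat-breadth type (`S`/`G`), occurrence sample size, predicted
#' current range area (units of 10 km^2), the full-dispersal (BCS) and
#' no-dispersal (WCS) range ratios under the CGCM2 A2 and B2 scenarios
#' expressed as `100 * future area / current area`, the trend class
#' (`W`inner / `L`oser / `C`olonizer), the centroid shift (km and bearing),
#' and two reference-range agreement percentages against IUCN ranges.
#' Colonizers have no current range, so their full-dispersal entry is an
#' absolute area (`area_bcs_*`) and the ratios are `NA`.
#'
#' `load_table2_fixture()` returns the climate-severity experiment table:
#' per species, the single most explanatory variable, the single-variable
#' current range area, and the percent range change when the future change
#' in that variable is applied once and doubled.
#'
#' @return A tibble (61 rows).
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1.csv", package = "nichecast")
  if (path == "" || !file.exists(path)) {
    abort("table1 fixture not found", class = "nc_fixture_error")
  }
  required <- c("species", "order", "type", "n", "area_2000",
                "ratio_full_a2", "ratio_nodisp_a2", "area_bcs_a2", "trend_a2",
                "ratio_full_b2", "ratio_nodisp_b2", "area_bcs_b2", "trend_b2",
                "shift_km", "shift_bearing_deg",
                "pct_iucn_covered", "pct_pred_in_iucn")
  t1 <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(required %in% names(t1)) || nrow(t1) != 61 ||
      anyNA(t1$species) || !all(t1$type %in% c("S", "G")) ||
      !all(t1$trend_a2 %in% c("W", "L", "C"))) {
    abort("table1 fixture is malformed", class = "nc_fixture_error")
  }
  t1
}

#' @rdname load_table1_fixture
#' @export
load_table2_fixture <- function() {
  path <- system.file("extdata", "table2.csv", package = "nichecast")
  if (path == "" || !file.exists(path)) {
    abort("table2 fixture not found", class = "nc_fixture_error")
  }
  t2 <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("species", "trend_a2", "variable", "area_2000",
                "pct_change_1x", "pct_change_2x")
  if (!all(required %in% names(t2)) || nrow(t2) != 61) {
    abort("table2 fixture is malformed", class = "nc_fixture_error")
  }
  t2
}

#' Published species-interaction role map
#'
#' The predator and competitor sets used in the community-overlap analyses:
#' the ten potential mammalian predators of the tundra vole, the European
#' hare as competitor of the mountain hare, and the grey wolf and brown
#' bear as co-occurring large predators of the European roe deer.
#'
#' @return A tibble with columns `focal`, `role` (`"predator"` or
#'   `"competitor"`), `partner`.
#' @export
load_roles_fixture <- function() {
  path <- system.file("extdata", "roles.csv", package = "nichecast")
  if (path == "" || !file.exists(path)) {
    abort("roles fixture not found", class = "nc_fixture_error")
  }
  readr::read_csv(path, show_col_types = FALSE)
}
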
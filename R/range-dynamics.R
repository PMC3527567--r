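#' Range under the no-dispersal (worst-case) scenario
#'
#' With no dispersal a species persists only where its predicted current
#' and future ranges overlap: the cell-wise intersection. The same
#' intersection, read as habitat that remains suitable, is the "stable
#' area" of the community analyses ([stable_area()] is an alias).
#'
#' @param current,future [binary_range()] objects on the same grid.
#' @return A [binary_range()].
#' @export
wcs_range <- function(current, future) {
  check_same_grid(current, future)
  binary_range(current$cells & future$cells, current$cell_km,
               region = current$region)
}

#' Classify a species' range trend
#'
#' Compares the current area with the full-dispersal future area:
#' `"C"` (colonizer) when a species with no current range gains one,
#' `"W"` (winner) when the range grows, `"L"` (loser) when it shrinks,
#' `"0"` for an exactly unchanged positive range (flagged by a warning;
#' the published table has no such case) and `"absent"` when both areas
#' are zero.
#'
#' @param area_current,area_bcs areas (any consistent unit), >= 0.
#' @return A single trend label.
#' @export
classify_trend <- function(area_current, area_bcs) {
  stopifnot(area_current >= 0, area_bcs >= 0)
  if (area_current == 0 && area_bcs == 0) {
    warn("species absent in both periods", class = "nc_trend_warning")
    return("absent")
  }
  if (area_current == 0) return("C")
  if (area_bcs > area_current) return("W")
  if (area_bcs < area_current) return("L")
  warn("range exactly unchanged", class = "nc_trend_warning")
  "0"
}

#' Centroid shift between two ranges
#'
#' The displacement between the unweighted centroids of the suitable cells
#' of two ranges, on the equal-area plane: distance in kilometres and
#' bearing in degrees clockwise from grid north, in \[0, 360). An exactly
#' zero shift has no bearing; it is reported as 0 with `zero_shift = TRUE`
#' to keep report files numeric.
#'
#' @param current,future non-empty [binary_range()] objects on the same
#'   grid.
#' @return A one-row tibble: `distance_km`, `bearing_deg`, `zero_shift`.
#' @export
centroid_shift <- function(current, future) {
  check_same_grid(current, future)
  if (sum(current$cells) == 0 || sum(future$cells) == 0) {
    abort("cannot take the centroid of an empty range",
          class = "nc_geometry_error")
  }
  ctr <- cell_centers(nrow(current$cells), ncol(current$cells),
                      current$cell_km)
  centroid <- function(r) {
    idx <- which(r$cells, arr.ind = TRUE)
    c(x = mean(ctr$x[idx[, 2]]), y = mean(ctr$y[idx[, 1]]))
  }
  dxy <- centroid(future) - centroid(current)
  d <- sqrt(sum(dxy^2))
  if (d < 1e-9) {
    return(tibble::tibble(distance_km = 0, bearing_deg = 0,
                          zero_shift = TRUE))
  }
  bearing <- (atan2(dxy[["x"]], dxy[["y"]]) * 180 / pi) %% 360
  tibble::tibble(distance_km = d, bearing_deg = bearing, zero_shift = FALSE)
}

#' Stacked species richness
#'
#' Per-cell count of species whose binary range includes the cell.
#'
#' @param ranges list of [binary_range()] objects on a shared grid.
#' @return Integer matrix.
#' @export
stack_richness <- function(ranges) {
  stopifnot(length(ranges) >= 1)
  for (r in ranges[-1]) check_same_grid(ranges[[1]], r)
  Reduce(`+`, lapply(ranges, function(r) r$cells + 0L))
}

#' Net change in summed suitability
#'
#' Bypasses binarization: per cell, the future minus current logistic
#' suitability, summed over species. Positive values mark cells whose
#' aggregate climatic suitability for the community improves.
#'
#' @param current_maps,future_maps lists of `nc_suitability` maps paired by
#'   name (species id).
#' @return Numeric matrix.
#' @export
net_suitability_change <- function(current_maps, future_maps) {
  if (is.null(names(current_maps)) || is.null(names(future_maps)) ||
      !setequal(names(current_maps), names(future_maps))) {
    abort("current and future maps must be paired by species name",
          class = "nc_pairing_error")
  }
  Reduce(`+`, lapply(names(current_maps), function(sp) {
    future_maps[[sp]]$logistic - current_maps[[sp]]$logistic
  }))
}

#' Per-species report row from projected ranges
#'
#' Assembles one row of the Table-1-schema report from the binary ranges of
#' one species: areas in units of 10 km^2, the full-dispersal ratio
#' `100 * A_BCS / A_0` and no-dispersal ratio `100 * A_WCS / A_0`, the
#' trend class, and the centroid shift; ratios are `NA` for colonizers.
#'
#' @param species species id.
#' @param current,future_bcs [binary_range()] objects; the WCS range is
#'   their intersection.
#' @param type habitat-breadth flag (`"S"`/`"G"`), carried through.
#' @param order taxonomic group label, carried through.
#' @return A one-row tibble.
#' @export
species_report <- function(species, current, future_bcs, type = NA_character_,
                           order = NA_character_) {
  wcs <- wcs_range(current, future_bcs)
  a0 <- range_area(current)
  ab <- range_area(future_bcs)
  aw <- range_area(wcs)
  trend <- suppressWarnings(classify_trend(a0, ab))
  shift <- if (a0 > 0 && ab > 0) {
    centroid_shift(current, future_bcs)
  } else {
    tibble::tibble(distance_km = NA_real_, bearing_deg = NA_real_,
                   zero_shift = NA)
  }
  tibble::tibble(
    species = species, order = order, type = type,
    area_current = a0, area_bcs = ab, area_wcs = aw,
    ratio_full = if (a0 > 0) 100 * ab / a0 else NA_real_,
    ratio_nodisp = if (a0 > 0) 100 * aw / a0 else NA_real_,
    trend = trend,
    shift_km = shift$distance_km, shift_bearing_deg = shift$bearing_deg
  )
}
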
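#' Community co-occurrence metrics
#'
#' Geometric overlap statistics between species ranges, all returned as
#' percentages of a focal area:
#'
#' * `stable_area()`: cells suitable both currently and in the future
#'   full-dispersal range — the part of a range a non-dispersing species
#'   can keep (identical to [wcs_range()] by definition).
#' * `fraction_with_at_least_k()`: share of a focal area where at least
#'   `k` of the listed ranges are suitable (e.g. "suitable for three or
#'   more potential predators").
#' * `overlap_fraction()`: share of range `a` also suitable for `b`
#'   (competitor encroachment).
#' * `cooccurrence_fraction()`: share of a reference region where all
#'   listed ranges co-occur (e.g. joint large-predator range).
#' * `predator_free_fraction()`: share of a prey range where none of the
#'   listed predator ranges is suitable; together with
#'   `fraction_with_at_least_k(k = 1)` it always sums to 100.
#'
#' @param current,future_bcs,a,b,area,region,prey [binary_range()] objects
#'   on a shared grid.
#' @param ranges,predators lists of [binary_range()] objects.
#' @param k minimum number of co-occurring ranges (>= 1).
#' @return `stable_area()` a [binary_range()]; the others a percentage in
#'   \[0, 100\].
#' @name community_metrics
NULL

#' @rdname community_metrics
#' @export
stable_area <- function(current, future_bcs) wcs_range(current, future_bcs)

count_grid <- function(area, ranges) {
  for (r in ranges) check_same_grid(area, r)
  if (length(ranges) == 0) {
    matrix(0L, nrow(area$cells), ncol(area$cells))
  } else {
    stack_richness(ranges)
  }
}

#' @rdname community_metrics
#' @export
fraction_with_at_least_k <- function(area, ranges, k = 1) {
  stopifnot(inherits(area, "nc_binary_range"), k >= 1)
  n <- sum(area$cells)
  if (n == 0) abort("focal area is empty", class = "nc_community_error")
  counts <- count_grid(area, ranges)
  100 * sum(counts[area$cells] >= k) / n
}

#' @rdname community_metrics
#' @export
overlap_fraction <- function(a, b) {
  check_same_grid(a, b)
  n <- sum(a$cells)
  if (n == 0) abort("focal range is empty", class = "nc_community_error")
  100 * sum(a$cells & b$cells) / n
}

#' @rdname community_metrics
#' @export
cooccurrence_fraction <- function(region, ranges) {
  stopifnot(inherits(region, "nc_binary_range"))
  if (length(ranges) == 0) abort("no ranges supplied",
                                 class = "nc_community_error")
  n <- sum(region$cells)
  if (n == 0) abort("region is empty", class = "nc_community_error")
  for (r in ranges) check_same_grid(region, r)
  joint <- Reduce(`&`, lapply(ranges, function(r) r$cells))
  100 * sum(joint & region$cells) / n
}

#' @rdname community_metrics
#' @export
predator_free_fraction <- function(prey, predators) {
  stopifnot(inherits(prey, "nc_binary_range"))
  n <- sum(prey$cells)
  if (n == 0) abort("prey range is empty", class = "nc_community_error")
  counts <- count_grid(prey, predators)
  100 * sum(counts[prey$cells] == 0) / n
}

#' Community overlap summary for one focal species
#'
#' Runs the overlap metrics for a focal species against a comparison set in
#' one period, returning tidy rows.
#'
#' @param focal focal species id.
#' @param focal_range [binary_range()] of the focal species.
#' @param comparison named list of [binary_range()] objects.
#' @param period period label carried into the result.
#' @param k threshold for the at-least-k metric.
#' @return A tibble with columns `focal`, `period`, `metric`, `value`,
#'   `n_cells`.
#' @export
community_overlap <- function(focal, focal_range, comparison,
                              period = "current", k = 3) {
  n <- sum(focal_range$cells)
  tibble::tibble(
    focal = focal, period = period,
    metric = c(paste0("fraction_with_at_least_", k),
               "predator_free_fraction"),
    value = c(fraction_with_at_least_k(focal_range, comparison, k = k),
              predator_free_fraction(focal_range, comparison)),
    n_cells = n
  )
}
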
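#' Thin occurrences to at most one record per grid cell
#'
#' Portal occurrence data are strongly clumped by sampling effort. Thinning
#' overlays a square grid of edge `cell_edge_km` and keeps at most one
#' record per cell, chosen uniformly at random, which flattens the effort
#' signal before model fitting. Records are canonically ordered before the
#' draw, so the result depends only on the record set and the seed, not on
#' input row order. The published protocol states the thinning raster as
#' "grid size 10 km^2", which is ambiguous between a 10-km edge and a
#' 10-km^2 area; the default here is a 10-km edge (use
#' `cell_edge_km = sqrt(10)` for the other reading).
#'
#' @param occ occurrence tibble with columns `x`, `y` (km).
#' @param cell_edge_km thinning-grid edge length in kilometres.
#' @param seed integer seed for the within-cell draw.
#' @return The thinned tibble with `status` set to `"thinned"`.
#' @export
thin_to_grid <- function(occ, cell_edge_km = 10, seed = 1L) {
  if (cell_edge_km <= 0) abort("cell_edge_km must be > 0",
                               class = "nc_config_error")
  if (nrow(occ) == 0) return(dplyr::mutate(occ, status = character(0)))
  if (nrow(occ) < 30) {
    warn(paste0("data are limited (<30 records, n = ", nrow(occ), ")"),
         class = "nc_sparse_data_warning")
  }
  occ <- dplyr::arrange(occ, .data$x, .data$y)
  cell <- paste(floor(occ$x / cell_edge_km), floor(occ$y / cell_edge_km))
  with_seed(seed, {
    keep <- unlist(lapply(split(seq_len(nrow(occ)), cell), function(idx) {
      if (length(idx) == 1L) idx else idx[sample.int(length(idx), 1L)]
    }), use.names = FALSE)
    dplyr::mutate(dplyr::arrange(occ[sort(keep), , drop = FALSE],
                                 .data$x, .data$y),
                  status = "thinned")
  })
}

#' Randomized train/test partition of occurrence records
#'
#' Sets aside `round(n * test_fraction)` records as test data (default 30%)
#' and keeps the rest for training, by simple random partition.
#'
#' @param occ occurrence tibble.
#' @param test_fraction fraction of records set aside, strictly in (0, 1).
#' @param seed integer seed.
#' @return A list with tibbles `train` and `test` (`status` updated); the
#'   two are disjoint and exhaust the input.
#' @export
split_train_test <- function(occ, test_fraction = 0.3, seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    abort("test_fraction must be in (0, 1)", class = "nc_config_error")
  }
  n <- nrow(occ)
  if (n < 2) abort("need at least 2 records to partition",
                   class = "nc_partition_error")
  n_test <- round(n * test_fraction)
  occ <- dplyr::arrange(occ, .data$x, .data$y)
  idx_test <- with_seed(seed, sample.int(n, n_test))
  list(
    train = dplyr::mutate(occ[setdiff(seq_len(n), idx_test), , drop = FALSE],
                          status = "train"),
    test = dplyr::mutate(occ[sort(idx_test), , drop = FALSE],
                         status = "test")
  )
}

#' Restrict occurrences and background to the calibration extent
#'
#' Mirrors the two-extent calibration strategy: models are calibrated on
#' the well-sampled subregion only (its occurrences and its cells as
#' background), because treating the under-sampled remainder as informed
#' absence would read lack of recording effort as unsuitability. Projection
#' still covers the full grid, so the returned stack keeps all layers and
#' the full region mask; only its calibration mask defines the background.
#'
#' @param occ occurrence tibble.
#' @param env an [env_stack()] with a calibration mask.
#' @return A list with `occurrences` (records inside the mask) and `env`
#'   (unchanged stack, carried for pipeline chaining).
#' @export
restrict_to_calibration <- function(occ, env) {
  stopifnot(inherits(env, "nc_env_stack"))
  if (sum(env$calibration) == 0) {
    abort("stack has an empty calibration mask", class = "nc_calibration_error")
  }
  d <- dim(env)
  cells <- xy_to_cell(occ$x, occ$y, d[1], d[2], env$cell_km)
  inside <- env$calibration[cbind(cells$row, cells$col)]
  if (!any(inside)) {
    abort("no occurrence record falls inside the calibration mask",
          class = "nc_calibration_error")
  }
  list(occurrences = occ[inside, , drop = FALSE], env = env)
}

#' Read and write occurrence CSV files
#'
#' The occurrence exchange dialect: a CSV with header
#' `species,x,y,date`, coordinates in kilometres on the equal-area plane.
#'
#' @param occ occurrence tibble.
#' @param path file path.
#' @return `write_occurrences()` returns `path` invisibly;
#'   `read_occurrences()` returns a tibble with `status = "raw"`.
#' @export
write_occurrences <- function(occ, path) {
  readr::write_csv(occ[, c("species", "x", "y", "date")], path)
  invisible(path)
}

#' @rdname write_occurrences
#' @export
read_occurrences <- function(path) {
  occ <- readr::read_csv(path, show_col_types = FALSE)
  dplyr::mutate(occ, status = "raw")
}
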
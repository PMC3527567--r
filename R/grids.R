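#' Environmental layer stacks and binary ranges
#'
#' `env_stack()` bundles co-registered single-band grids (one per
#' environmental variable) for one time period on an idealized equal-area
#' plane. Rows run north to south (row 1 is the northern edge), columns west
#' to east, and every cell is a square of `cell_km` kilometres on a side.
#' Two logical masks travel with the stack: `region`, the study region over
#' which ranges and richness are reported, and `calibration`, the
#' well-sampled subregion used to draw model background points (projection
#' always uses the full grid).
#'
#' @param layers named list of numeric matrices, all the same dimension.
#' @param cell_km cell edge length in kilometres.
#' @param period period label, e.g. `"current"`, `"future"`,
#'   `"future-doubled"`.
#' @param region,calibration logical matrices matching the layer dimensions.
#'   Defaults: `region` all `TRUE`; `calibration` equal to `region`.
#' @return An object of class `nc_env_stack`.
#' @export
env_stack <- function(layers, cell_km, period = "current",
                      region = NULL, calibration = NULL) {
  stopifnot(is.list(layers), length(layers) >= 1, !is.null(names(layers)))
  dims <- dim(layers[[1]])
  ok <- vapply(layers, function(l) identical(dim(l), dims), logical(1))
  if (!all(ok)) abort("all layers must share dimensions", class = "nc_grid_error")
  if (!is.numeric(cell_km) || cell_km <= 0) {
    abort("cell_km must be > 0", class = "nc_config_error")
  }
  region <- region %||% matrix(TRUE, dims[1], dims[2])
  calibration <- calibration %||% region
  stopifnot(identical(dim(region), dims), identical(dim(calibration), dims))
  bad <- vapply(layers, function(l) anyNA(l[region]), logical(1))
  if (any(bad)) {
    abort(paste("missing values inside the region mask in layer(s):",
                paste(names(layers)[bad], collapse = ", ")),
          class = "nc_grid_error")
  }
  structure(
    list(layers = layers, cell_km = cell_km, period = period,
         region = region, calibration = calibration),
    class = "nc_env_stack"
  )
}

#' @export
print.nc_env_stack <- function(x, ...) {
  d <- dim(x$layers[[1]])
  cat("<nc_env_stack> period:", x$period, "|", length(x$layers), "layers |",
      d[1], "x", d[2], "cells @", x$cell_km, "km |",
      sum(x$region), "region cells,", sum(x$calibration), "calibration cells\n")
  invisible(x)
}

#' @export
dim.nc_env_stack <- function(x) dim(x$layers[[1]])

env_layer_names <- function(env) names(env$layers)

#' Binary species range on a grid
#'
#' The unit of all range algebra: a logical grid of suitable cells plus the
#' cell-size metadata needed to express areas in units of 10 km^2 (the
#' reporting unit of the published tables; cell area in those units is
#' `cell_km^2 / 10`).
#'
#' @param cells logical matrix of suitable cells.
#' @param cell_km cell edge length in kilometres.
#' @param region optional logical region mask; suitable cells outside it are
#'   dropped.
#' @return An object of class `nc_binary_range`.
#' @export
binary_range <- function(cells, cell_km, region = NULL) {
  stopifnot(is.matrix(cells), is.logical(cells))
  if (!is.null(region)) {
    stopifnot(identical(dim(region), dim(cells)))
    cells <- cells & region
  }
  structure(list(cells = cells, cell_km = cell_km,
                 region = region %||% matrix(TRUE, nrow(cells), ncol(cells))),
            class = "nc_binary_range")
}

#' @export
print.nc_binary_range <- function(x, ...) {
  cat("<nc_binary_range>", sum(x$cells), "suitable cells of",
      length(x$cells), "| area", format(range_area(x)), "x 10 km^2\n")
  invisible(x)
}

#' Range area in units of 10 km^2
#'
#' @param range an [binary_range()] object.
#' @return Numeric scalar: suitable-cell count times `cell_km^2 / 10`.
#' @export
range_area <- function(range) {
  stopifnot(inherits(range, "nc_binary_range"))
  sum(range$cells) * range$cell_km^2 / 10
}

check_same_grid <- function(a, b) {
  if (!identical(dim(a$cells), dim(b$cells)) ||
      !isTRUE(all.equal(a$cell_km, b$cell_km))) {
    abort("ranges are not on the same grid", class = "nc_grid_error")
  }
}

# Cell-center coordinates in km. Row 1 is the northern edge, so y decreases
# with row index; x increases with column index.
cell_centers <- function(nrow, ncol, cell_km) {
  list(x = (seq_len(ncol) - 0.5) * cell_km,
       y = (nrow - seq_len(nrow) + 0.5) * cell_km)
}

# Map continuous km coordinates to (row, col); points on a cell boundary
# belong to the cell north/east of it, clamped to the grid.
xy_to_cell <- function(x, y, nrow, ncol, cell_km) {
  col <- pmin(pmax(floor(x / cell_km) + 1L, 1L), ncol)
  row <- pmin(pmax(nrow - floor(y / cell_km), 1L), nrow)
  list(row = as.integer(row), col = as.integer(col))
}

#' Read and write grids as ESRI ASCII rasters
#'
#' Plain-text georeferenced grid exchange: one `.asc` file per layer per
#' period, readable by every GIS. The grid origin is the south-west corner
#' at (0, 0) on the equal-area plane; cell size is in kilometres.
#'
#' @param grid numeric matrix (row 1 = north).
#' @param path file path.
#' @param cell_km cell edge length in kilometres.
#' @param na_value value standing in for missing cells in the file.
#' @return `write_ascii_grid()` returns `path` invisibly;
#'   `read_ascii_grid()` returns a list with `grid` and `cell_km`.
#' @export
write_ascii_grid <- function(grid, path, cell_km, na_value = -9999) {
  stopifnot(is.matrix(grid))
  header <- c(
    paste("ncols", ncol(grid)),
    paste("nrows", nrow(grid)),
    "xllcorner 0",
    "yllcorner 0",
    paste("cellsize", cell_km),
    paste("NODATA_value", na_value)
  )
  body <- apply(grid, 1, function(r) {
    r[is.na(r)] <- na_value
    paste(format(r, trim = TRUE, scientific = FALSE, digits = 10),
          collapse = " ")
  })
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  vals <- setNames(vapply(hdr, function(h) as.numeric(h[2]), numeric(1)),
                   vapply(hdr, `[`, character(1), 1))
  grid <- do.call(rbind, lapply(lines[-(1:6)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  grid[grid == vals[["nodata_value"]]] <- NA
  stopifnot(nrow(grid) == vals[["nrows"]], ncol(grid) == vals[["ncols"]])
  list(grid = grid, cell_km = vals[["cellsize"]])
}
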
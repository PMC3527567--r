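#' Configure a synthetic (sub)arctic landscape
#'
#' Defines the virtual study system: a rectangular equal-area grid carrying
#' spatially autocorrelated climate and vegetation-biomass layers for a
#' "current" period, plus an additive per-layer change field describing a
#' warming scenario. Each layer is
#' `gradient * southness + noise_amplitude * field`, where `southness` runs
#' 0 at the northern edge to 1 at the southern edge (so climate layers read
#' like temperatures: warmer south) and `field` is a unit-variance Gaussian
#' random field obtained by Gaussian-kernel smoothing of white noise with
#' bandwidth `autocorr_km`. Layers share a common correlation structure via
#' `correlation`. The scenario field is
#' `delta * (1 + delta_gradient * (northness - 0.5))`: uniform warming plus
#' a latitudinal component, amplified toward the north as in high-latitude
#' projections.
#'
#' Two labelled subregions mirror the study design: a "well-sampled"
#' calibration subregion (the western `calibration_frac` of the grid,
#' standing in for Fennoscandia) and an under-sampled remainder (standing in
#' for north-western Russia). The southern `buffer_frac` of the grid is a
#' buffer outside the study region that admits potential colonizers.
#'
#' @param nrow,ncol grid dimensions in cells (at least 2 x 2).
#' @param cell_km cell edge length in kilometres (default 10).
#' @param n_climate,n_veg number of climate (default 19) and vegetation
#'   (default 4) layers, named `bio1...` and `veg1...`.
#' @param autocorr_km spatial autocorrelation range (Gaussian kernel
#'   bandwidth) in kilometres.
#' @param correlation inter-layer correlation matrix
#'   (`n_climate + n_veg` square, symmetric positive semi-definite), or a
#'   single scalar giving an exchangeable correlation. Default 0.3,
#'   reflecting the strong collinearity of bioclim summaries.
#' @param gradient per-layer amplitude of the deterministic north-south
#'   surface (recycled); default 4 for climate layers, 2 for vegetation.
#' @param noise_amplitude per-layer standard deviation of the stochastic
#'   field (recycled; 0 gives purely deterministic layers).
#' @param delta per-layer scenario change (recycled); default +1 for climate
#'   layers and +0.5 for vegetation, i.e. roughly a quarter of the
#'   north-to-south contrast by 2080.
#' @param delta_gradient relative strength of the latitudinal component of
#'   the change field (0 = spatially uniform change).
#' @param calibration_frac western fraction of columns forming the
#'   well-sampled calibration subregion.
#' @param buffer_frac southern fraction of rows outside the study region.
#' @param seed integer seed; the same seed yields bit-identical current and
#'   future stacks (the future stack differs only by the delta field).
#' @return An object of class `nc_landscape_config` (a validated list).
#' @export
landscape_config <- function(nrow = 120, ncol = 120, cell_km = 10,
                             n_climate = 19, n_veg = 4,
                             autocorr_km = 50, correlation = 0.3,
                             gradient = NULL, noise_amplitude = 1,
                             delta = NULL, delta_gradient = 0.5,
                             calibration_frac = 0.5, buffer_frac = 0.25,
                             seed = 1L) {
  if (nrow < 2 || ncol < 2) abort("grid must be at least 2 x 2",
                                  class = "nc_config_error")
  if (cell_km <= 0) abort("cell_km must be > 0", class = "nc_config_error")
  n_layers <- n_climate + n_veg
  if (is.matrix(correlation)) {
    C <- correlation
  } else {
    C <- matrix(correlation, n_layers, n_layers)
    diag(C) <- 1
  }
  if (!isTRUE(all.equal(C, t(C))) || min(eigen(C, symmetric = TRUE,
                                               only.values = TRUE)$values) < -1e-8) {
    abort("correlation matrix must be symmetric positive semi-definite",
          class = "nc_config_error")
  }
  layer_names <- c(if (n_climate > 0) paste0("bio", seq_len(n_climate)),
                   if (n_veg > 0) paste0("veg", seq_len(n_veg)))
  gradient <- gradient %||% c(rep(4, n_climate), rep(2, n_veg))
  delta <- delta %||% c(rep(1, n_climate), rep(0.5, n_veg))
  structure(
    list(nrow = as.integer(nrow), ncol = as.integer(ncol), cell_km = cell_km,
         n_climate = n_climate, n_veg = n_veg, layer_names = layer_names,
         autocorr_km = autocorr_km, correlation = C,
         gradient = rep_len(gradient, n_layers),
         noise_amplitude = rep_len(noise_amplitude, n_layers),
         delta = rep_len(delta, n_layers), delta_gradient = delta_gradient,
         calibration_frac = calibration_frac, buffer_frac = buffer_frac,
         seed = as.integer(seed)),
    class = "nc_landscape_config"
  )
}

# Row-stochastic Gaussian smoothing matrix over n positions; bandwidth in
# cells. Row normalization keeps edge cells unbiased.
gaussian_smoother <- function(n, sigma_cells) {
  if (sigma_cells <= 0) return(diag(n))
  K <- outer(seq_len(n), seq_len(n), function(i, j) {
    dnorm((i - j) / sigma_cells)
  })
  K / rowSums(K)
}

# One unit-variance autocorrelated field per layer, mixed to the target
# inter-layer correlation. Returns a (ncell x nlayers) matrix.
correlated_fields <- function(config) {
  n_layers <- length(config$layer_names)
  ncell <- config$nrow * config$ncol
  Kr <- gaussian_smoother(config$nrow, config$autocorr_km / config$cell_km)
  Kc <- gaussian_smoother(config$ncol, config$autocorr_km / config$cell_km)
  white <- matrix(rnorm(ncell * n_layers), ncell, n_layers)
  # planar-detrend each field: smoothing white noise leaves strong
  # domain-scale modes, which would tilt the landscape's isoclines away
  # from the configured gradient; texture stays, trends are imposed only
  # through `gradient` and `delta`
  row_c <- rep(seq_len(config$nrow), config$ncol) - (config$nrow + 1) / 2
  col_c <- rep(seq_len(config$ncol), each = config$nrow) - (config$ncol + 1) / 2
  smooth <- apply(white, 2, function(w) {
    f <- as.vector(Kr %*% matrix(w, config$nrow, config$ncol) %*% t(Kc))
    f <- f - mean(f) - row_c * sum(f * row_c) / sum(row_c^2) -
      col_c * sum(f * col_c) / sum(col_c^2)
    f / max(sd(f), 1e-12)
  })
  ev <- eigen(config$correlation, symmetric = TRUE)
  mix <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), length(ev$values)) %*%
    t(ev$vectors)
  smooth %*% mix
}

landscape_surfaces <- function(config) {
  # southness: 0 at the northern edge (row 1), 1 at the southern edge
  southness <- matrix(rep((seq_len(config$nrow) - 0.5) / config$nrow,
                          config$ncol), config$nrow, config$ncol)
  northness <- 1 - southness
  list(southness = southness, northness = northness)
}

landscape_masks <- function(config) {
  region <- matrix(TRUE, config$nrow, config$ncol)
  n_buffer <- floor(config$buffer_frac * config$nrow)
  if (n_buffer > 0) {
    region[(config$nrow - n_buffer + 1):config$nrow, ] <- FALSE
  }
  calibration <- matrix(FALSE, config$nrow, config$ncol)
  n_west <- max(1L, round(config$calibration_frac * config$ncol))
  calibration[, seq_len(n_west)] <- TRUE
  list(region = region, calibration = calibration)
}

#' Generate a synthetic environmental stack
#'
#' Realizes the landscape described by a [landscape_config()] for one
#' period. The stochastic fields depend only on the config seed, so the
#' future stack equals the current stack plus the configured delta field
#' exactly, cell by cell.
#'
#' @param config a [landscape_config()].
#' @param period `"current"` or `"future"`.
#' @return An [env_stack()].
#' @export
generate_env_stack <- function(config, period = c("current", "future")) {
  stopifnot(inherits(config, "nc_landscape_config"))
  period <- match.arg(period)
  fields <- with_seed(config$seed, correlated_fields(config))
  surf <- landscape_surfaces(config)
  masks <- landscape_masks(config)
  delta_shape <- 1 + config$delta_gradient * (surf$northness - 0.5)
  layers <- lapply(seq_along(config$layer_names), function(i) {
    base <- config$gradient[i] * surf$southness +
      config$noise_amplitude[i] * matrix(fields[, i], config$nrow, config$ncol)
    if (period == "future") base <- base + config$delta[i] * delta_shape
    base
  })
  names(layers) <- config$layer_names
  env_stack(layers, cell_km = config$cell_km, period = period,
            region = masks$region, calibration = masks$calibration)
}

#' Scenario delta field for one layer
#'
#' The additive change field a [landscape_config()] imposes between the
#' current and future periods.
#'
#' @param config a [landscape_config()].
#' @param layer layer name.
#' @return Numeric matrix.
#' @export
scenario_delta_field <- function(config, layer) {
  i <- match(layer, config$layer_names)
  if (is.na(i)) abort(paste("unknown layer:", layer), class = "nc_config_error")
  surf <- landscape_surfaces(config)
  config$delta[i] * (1 + config$delta_gradient * (surf$northness - 0.5))
}

#' Resample a coarse grid to a finer resolution
#'
#' Upsamples a coarse-resolution grid (e.g. vegetation biomass supplied at a
#' coarser scale than the climate layers) onto a finer grid whose dimensions
#' are integer multiples of the coarse ones. `"nearest"` replicates each
#' coarse cell over its block of fine cells; `"linear"` interpolates
#' bilinearly between coarse cell centers, so interior fine values are
#' convex combinations of the surrounding coarse nodes.
#'
#' @param coarse_grid numeric matrix.
#' @param fine_shape integer vector `c(nrow, ncol)` of the target grid.
#' @param method `"nearest"` or `"linear"`.
#' @return Numeric matrix of dimension `fine_shape`.
#' @export
resample_vegetation <- function(coarse_grid, fine_shape,
                                method = c("linear", "nearest")) {
  method <- match.arg(method)
  stopifnot(is.matrix(coarse_grid), length(fine_shape) == 2)
  fr <- fine_shape[1] / nrow(coarse_grid)
  fc <- fine_shape[2] / ncol(coarse_grid)
  if (fr != round(fr) || fc != round(fc) || fr < 1 || fc < 1) {
    abort("fine shape must be an integer multiple of the coarse shape",
          class = "nc_resample_error")
  }
  if (method == "nearest") {
    return(coarse_grid[rep(seq_len(nrow(coarse_grid)), each = fr),
                       rep(seq_len(ncol(coarse_grid)), each = fc),
                       drop = FALSE])
  }
  # bilinear on cell centers, clamped at the border half-cells
  interp_pos <- function(n_fine, factor, n_coarse) {
    pos <- ((seq_len(n_fine) - 0.5) / factor) - 0.5   # coarse node coordinate
    pos <- pmin(pmax(pos, 0), n_coarse - 1)
    i0 <- pmin(floor(pos), n_coarse - 2)
    if (n_coarse == 1) i0 <- rep(0, n_fine)
    list(i0 = as.integer(i0) + 1L, w = pos - i0)
  }
  r <- interp_pos(fine_shape[1], fr, nrow(coarse_grid))
  cc <- interp_pos(fine_shape[2], fc, ncol(coarse_grid))
  r1 <- pmin(r$i0 + 1L, nrow(coarse_grid))
  c1 <- pmin(cc$i0 + 1L, ncol(coarse_grid))
  wr <- matrix(r$w, fine_shape[1], fine_shape[2])
  wc <- matrix(cc$w, fine_shape[1], fine_shape[2], byrow = TRUE)
  g00 <- coarse_grid[r$i0, cc$i0, drop = FALSE]
  g10 <- coarse_grid[r1, cc$i0, drop = FALSE]
  g01 <- coarse_grid[r$i0, c1, drop = FALSE]
  g11 <- coarse_grid[r1, c1, drop = FALSE]
  g00 * (1 - wr) * (1 - wc) + g10 * wr * (1 - wc) +
    g01 * (1 - wr) * wc + g11 * wr * wc
}
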
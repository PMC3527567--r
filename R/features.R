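#' Build a model feature set from an environmental stack
#'
#' Expands the raw layers into the model's feature space. Every non-constant
#' layer contributes a linear and a quadratic feature; when the presence
#' sample exceeds 15 records, each layer additionally contributes hinge
#' features of both orientations with knots at evenly spaced background
#' quantiles, giving the response curves their flexibility. All features are
#' min-max normalized to \[0, 1\] over the background (the calibration-mask
#' cells), which also defines the clamping range used at projection time.
#' Layers that are constant over the background carry no information and
#' are dropped with a warning.
#'
#' Feature value definitions, for a raw layer value v with background range
#' \[lo, hi\]:
#' linear `(v - lo) / (hi - lo)`; quadratic the square of the linear
#' feature; forward hinge `(v - k) / (hi - k)` above the knot k and 0 below;
#' reverse hinge `(k - v) / (k - lo)` below the knot and 0 above.
#'
#' @param env an [env_stack()]; the background is its calibration mask.
#' @param presence_count number of presence records the model will be fitted
#'   to; hinge features are added only when this exceeds 15.
#' @param hinge_knot_count knots per layer and orientation (default 5).
#' @return An object of class `nc_feature_set`: a tibble of feature
#'   definitions plus the layer names used.
#' @export
build_features <- function(env, presence_count, hinge_knot_count = 5) {
  stopifnot(inherits(env, "nc_env_stack"), presence_count >= 1)
  bg <- env$calibration
  defs <- purrr::map(env_layer_names(env), function(nm) {
    v <- env$layers[[nm]][bg]
    lo <- min(v); hi <- max(v)
    if (hi - lo < 1e-12) {
      warn(paste("layer", nm, "is constant over the background; dropped"),
           class = "nc_constant_layer_warning")
      return(NULL)
    }
    base <- tibble::tibble(
      layer = nm, class = c("linear", "quadratic"),
      knot = NA_real_, orientation = NA_character_, lower = lo, upper = hi
    )
    if (presence_count > 15 && hinge_knot_count > 0) {
      probs <- seq_len(hinge_knot_count) / (hinge_knot_count + 1)
      knots <- unname(quantile(v, probs, type = 7))
      knots <- knots[knots > lo & knots < hi]
      if (length(knots) > 0) {
        base <- dplyr::bind_rows(
          base,
          tibble::tibble(layer = nm, class = "hinge", knot = rep(knots, 2),
                         orientation = rep(c("fwd", "rev"),
                                           each = length(knots)),
                         lower = lo, upper = hi)
        )
      }
    }
    base
  })
  defs <- dplyr::bind_rows(defs)
  if (nrow(defs) == 0) abort("no usable layers", class = "nc_feature_error")
  defs$feature <- paste0(
    defs$layer, "_", defs$class,
    ifelse(is.na(defs$knot), "",
           paste0("_", defs$orientation, "_",
                  formatC(defs$knot, format = "g", digits = 6)))
  )
  defs$beta <- NA_real_
  structure(list(defs = defs, layers = unique(defs$layer)),
            class = "nc_feature_set")
}

#' @export
print.nc_feature_set <- function(x, ...) {
  cat("<nc_feature_set>", nrow(x$defs), "features over",
      length(x$layers), "layers (",
      paste(names(table(x$defs$class)), table(x$defs$class),
            sep = ":", collapse = " "), ")\n")
  invisible(x)
}

# Evaluate the feature set on a matrix of raw layer values
# (cells x layers, columns named). With clamp = TRUE feature values are
# truncated to the training [0, 1] range and an attribute "clamped" marks
# rows where truncation occurred.
feature_matrix <- function(fs, values, clamp = FALSE) {
  stopifnot(inherits(fs, "nc_feature_set"))
  missing <- setdiff(fs$layers, colnames(values))
  if (length(missing) > 0) {
    abort(paste("missing layer(s):", paste(missing, collapse = ", ")),
          class = "nc_projection_error")
  }
  defs <- fs$defs
  F <- matrix(0, nrow(values), nrow(defs),
              dimnames = list(NULL, defs$feature))
  for (j in seq_len(nrow(defs))) {
    v <- values[, defs$layer[j]]
    F[, j] <- switch(defs$class[j],
      linear = (v - defs$lower[j]) / (defs$upper[j] - defs$lower[j]),
      quadratic = ((v - defs$lower[j]) / (defs$upper[j] - defs$lower[j]))^2,
      hinge = if (defs$orientation[j] == "fwd") {
        pmax(0, (v - defs$knot[j]) / (defs$upper[j] - defs$knot[j]))
      } else {
        pmax(0, (defs$knot[j] - v) / (defs$knot[j] - defs$lower[j]))
      }
    )
  }
  if (!all(is.finite(F))) {
    abort("non-finite feature values", class = "nc_fitting_error")
  }
  if (clamp) {
    clamped <- rowSums(F < 0 | F > 1) > 0
    F[F < 0] <- 0
    F[F > 1] <- 1
    attr(F, "clamped") <- clamped
  }
  F
}

# Raw layer values at a set of cell indices as a (cells x layers) matrix.
stack_values <- function(env, cells, layers = env_layer_names(env)) {
  vals <- vapply(layers, function(nm) env$layers[[nm]][cells],
                 numeric(length(cells)))
  if (length(cells) == 1L) vals <- matrix(vals, 1, dimnames = list(NULL, layers))
  vals
}

# Published per-class default regularization multipliers, interpolated in
# the presence sample size m (linear/quadratic; hinge is constant 0.5).
beta_default <- function(class, m) {
  lq <- stats::approx(x = c(0, 10, 30, 100),
                      y = c(1, 1, 0.2, 0.05),
                      xout = min(m, 100), rule = 2)$y
  ifelse(class == "hinge", 0.5, lq)
}
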
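#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted niche model
#'
#' One row per feature with its coefficient and penalty; `active` marks
#' features the L1 penalty left in the model.
#'
#' @param x an `nc_maxent`.
#' @param ... unused.
#' @return A tibble: `term`, `layer`, `class`, `estimate`, `penalty`,
#'   `active`.
#' @export
tidy.nc_maxent <- function(x, ...) {
  defs <- if (!is.null(x$features)) {
    x$features$defs
  } else {
    tibble::tibble(feature = names(x$lambda) %||%
                     paste0("f", seq_along(x$lambda)),
                   layer = NA_character_, class = NA_character_)
  }
  tibble::tibble(
    term = defs$feature, layer = defs$layer, class = defs$class,
    estimate = unname(x$lambda), penalty = unname(x$beta),
    active = unname(x$lambda) != 0
  )
}

#' Fit-level summary of a niche model
#'
#' @param x an `nc_maxent`.
#' @param ... unused.
#' @return A one-row tibble: sample sizes, feature counts, iterations,
#'   final objective, entropy, convergence flag.
#' @export
glance.nc_maxent <- function(x, ...) {
  tibble::tibble(
    n_presence = x$n_presence, n_background = x$n_background,
    n_features = length(x$lambda), n_active = sum(x$lambda != 0),
    iterations = x$iterations, objective = x$objective,
    entropy = x$entropy, converged = x$converged
  )
}
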
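#' Training AUC of each single-variable model
#'
#' Fits one model per environmental layer using that layer alone (same
#' feature rules as the full model) and scores it by training AUC against
#' the background. This ranks the layers by how much each explains on its
#' own.
#'
#' @param occ training occurrence tibble.
#' @param env an [env_stack()].
#' @param hinge_knot_count,beta_scale,convergence,max_iter,background_size,seed
#'   passed to [fit_species_model()].
#' @return A tibble with columns `layer`, `auc`, sorted by layer name.
#' @export
single_variable_aucs <- function(occ, env, hinge_knot_count = 5,
                                 beta_scale = 1, convergence = 1e-6,
                                 max_iter = 500, background_size = 10000,
                                 seed = 1L) {
  layers <- sort(env_layer_names(env))
  rows <- purrr::map(layers, function(nm) {
    a <- tryCatch({
      model <- fit_species_model(occ, env, layers = nm,
                                 hinge_knot_count = hinge_knot_count,
                                 beta_scale = beta_scale,
                                 convergence = convergence,
                                 max_iter = max_iter,
                                 background_size = background_size,
                                 seed = seed)
      d <- dim(env)
      vals_p <- stack_values(env, model$presence_cells, layers = nm)
      vals_b <- stack_values(env, model$background, layers = nm)
      eta_p <- as.vector(feature_matrix(model$features, vals_p) %*%
                           model$lambda)
      eta_b <- as.vector(feature_matrix(model$features, vals_b) %*%
                           model$lambda)
      auc(eta_p, eta_b)
    }, nc_constant_layer_warning = function(w) NA_real_,
       nc_feature_error = function(e) NA_real_)
    tibble::tibble(layer = nm, auc = a)
  })
  dplyr::bind_rows(rows)
}

#' Most explanatory environmental variable
#'
#' The layer whose single-variable model attains the highest training AUC.
#' Exact ties (and the degenerate case of every AUC at 0.5 or below) break
#' to the first layer in name order, deterministically.
#'
#' @inheritParams single_variable_aucs
#' @return A one-row tibble: `variable`, `auc`, `degenerate`.
#' @export
top_variable <- function(occ, env, ...) {
  if (length(env$layers) < 2) abort("need at least 2 layers",
                                    class = "nc_config_error")
  tab <- single_variable_aucs(occ, env, ...)
  usable <- tab[!is.na(tab$auc), , drop = FALSE]
  if (nrow(usable) == 0) abort("no usable layers", class = "nc_feature_error")
  degenerate <- all(usable$auc <= 0.5 + 1e-9)
  best <- usable$auc >= max(usable$auc) - 1e-12
  i <- which(best)[1]  # layers already sorted by name
  tibble::tibble(variable = usable$layer[i], auc = usable$auc[i],
                 degenerate = degenerate)
}

#' Amplify the scenario change in one variable
#'
#' Builds the counterfactual "more severe" stack: identical to `future`
#' except that layer `variable` is replaced by
#' `current + 2 * (future - current)`, doubling its change field.
#'
#' @param current,future [env_stack()] objects sharing `variable`.
#' @param variable layer name.
#' @return An [env_stack()] labelled `"future-doubled"`.
#' @export
doubled_delta_stack <- function(current, future, variable) {
  if (!variable %in% env_layer_names(current) ||
      !variable %in% env_layer_names(future)) {
    abort(paste("variable not present in both stacks:", variable),
          class = "nc_grid_error")
  }
  layers <- future$layers
  layers[[variable]] <- current$layers[[variable]] +
    2 * (future$layers[[variable]] - current$layers[[variable]])
  env_stack(layers, future$cell_km, period = "future-doubled",
            region = future$region, calibration = future$calibration)
}

#' Classify climate-severity outcomes
#'
#' Joins per-species areas under the 1x and 2x change scenarios and flags
#' the qualitative outcomes: `extinct` (a resident whose 2x future area is
#' zero), `colonization_failure` (a colonizer whose 2x future area is
#' zero), `loss_over_90` (a resident losing more than 90% of its current
#' range at 2x), and `sign_reversal` (percent change flipping sign between
#' 1x and 2x).
#'
#' @param reports_1x,reports_2x tibbles with columns `species`,
#'   `area_current`, `area_future` (areas from the single-variable models
#'   at the two severities; `area_current` must agree).
#' @return A tibble with per-species percent changes and outcome flags.
#' @export
severity_outcomes <- function(reports_1x, reports_2x) {
  if (!setequal(reports_1x$species, reports_2x$species)) {
    abort("unpaired species between the 1x and 2x reports",
          class = "nc_pairing_error")
  }
  joined <- dplyr::inner_join(
    dplyr::rename(reports_1x, area_1x = "area_future"),
    dplyr::select(dplyr::rename(reports_2x, area_2x = "area_future"),
                  "species", "area_2x"),
    by = "species"
  )
  pct <- function(a0, a1) ifelse(a0 > 0, 100 * (a1 - a0) / a0, NA_real_)
  dplyr::mutate(
    joined,
    resident = .data$area_current > 0,
    pct_change_1x = pct(.data$area_current, .data$area_1x),
    pct_change_2x = pct(.data$area_current, .data$area_2x),
    extinct = .data$resident & .data$area_2x == 0,
    colonization_failure = !.data$resident & .data$area_2x == 0,
    loss_over_90 = .data$resident & !.data$extinct &
      (.data$area_current - .data$area_2x) / .data$area_current > 0.9,
    sign_reversal = .data$resident &
      sign(.data$pct_change_1x) * sign(.data$pct_change_2x) == -1
  )
}

#' Run the severity experiment for one species
#'
#' Identifies the most explanatory variable, fits the single-variable
#' model, thresholds it on the current stack, and projects it onto the
#' future stack and the doubled-change stack. The 1x threshold is reused
#' at 2x: a counterfactual scenario offers no data to re-fit one. Clamping
#' stays on — values far outside the training range are exactly where
#' extinctions emerge — and the clamped cell counts are reported.
#'
#' @param occ training occurrences.
#' @param env_current,env_future [env_stack()] objects.
#' @param ... passed to [single_variable_aucs()] and [fit_species_model()].
#' @return A one-row tibble: `species`, `variable`, `area_current`,
#'   `area_1x`, `area_2x`, `pct_change_1x`, `pct_change_2x`, clamped cell
#'   counts.
#' @export
severity_experiment <- function(occ, env_current, env_future, ...) {
  tv <- top_variable(occ, env_current, ...)
  model <- fit_species_model(occ, env_current, layers = tv$variable, ...)
  bg_scores <- function(map) map$logistic[model$background]
  map0 <- project(model, env_current)
  thr <- select_threshold(score_occurrences(map0, occ), bg_scores(map0))
  env_2x <- doubled_delta_stack(env_current, env_future, tv$variable)
  map1 <- project(model, env_future)
  map2 <- project(model, env_2x)
  r0 <- binarize(map0, thr$threshold)
  r1 <- binarize(map1, thr$threshold)
  r2 <- binarize(map2, thr$threshold)
  a0 <- range_area(r0)
  pct <- function(a) if (a0 > 0) 100 * (a - a0) / a0 else NA_real_
  tibble::tibble(
    species = occ$species[1], variable = tv$variable,
    area_current = a0, area_1x = range_area(r1), area_2x = range_area(r2),
    pct_change_1x = pct(range_area(r1)), pct_change_2x = pct(range_area(r2)),
    clamped_1x = sum(map1$clamped), clamped_2x = sum(map2$clamped)
  )
}
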
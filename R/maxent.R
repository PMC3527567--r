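#' Fit a presence-background maximum-entropy niche model
#'
#' Fits the Gibbs distribution `q(x) = exp(lambda . f(x)) / Z` over the
#' background cells by minimizing the L1-penalized negative presence
#' log-likelihood
#' `-(1/m) sum_i lambda . f(x_i) + log Z + sum_j beta_j |lambda_j|`,
#' the standard maxent objective for presence-background data. The
#' optimizer is deterministic cyclic coordinate descent: each feature takes
#' a quadratic-approximation step soft-thresholded by its penalty, with
#' backtracking halving so the exact objective never increases. Iteration
#' stops when a full sweep changes the objective by less than `convergence`
#' (default 1e-6) or after `max_iter` sweeps (default 500).
#'
#' Per-feature penalties default to the published per-class maxent
#' regularization (interpolated in sample size for linear/quadratic
#' features, 0.5 for hinge) times the presence-sample standard deviation of
#' the feature over `sqrt(m)`, scaled by `beta_scale`; a small positive
#' floor keeps every penalty strictly positive, which also prevents
#' perfect-separation blow-up.
#'
#' @param presences numeric matrix of presence feature rows (m x J), e.g.
#'   from [feature_matrix()].
#' @param background numeric matrix of background feature rows (n x J,
#'   n >= 2), same columns.
#' @param features optional [build_features()] result; stored in the model
#'   (with fitted penalties) so it can be projected onto new stacks.
#' @param beta_scale positive multiplier on all penalties.
#' @param beta optional explicit per-feature penalty vector overriding the
#'   defaults.
#' @param convergence objective-change tolerance terminating the fit.
#' @param max_iter maximum number of coordinate-descent sweeps.
#' @return An object of class `nc_maxent`: feature set, coefficients
#'   `lambda`, the background log-partition value, the entropy `H` of the
#'   fitted background distribution, and fit metadata (`iterations`,
#'   `objective`, `converged`).
#' @export
fit_maxent <- function(presences, background, features = NULL,
                       beta_scale = 1, beta = NULL,
                       convergence = 1e-6, max_iter = 500) {
  presences <- as.matrix(presences)
  background <- as.matrix(background)
  m <- nrow(presences); n <- nrow(background)
  if (m < 1) abort("need at least one presence", class = "nc_fitting_error")
  if (n < 2) abort("need at least 2 background rows",
                   class = "nc_fitting_error")
  if (ncol(presences) != ncol(background)) {
    abort("presence and background feature spaces differ",
          class = "nc_fitting_error")
  }
  if (!all(is.finite(presences)) || !all(is.finite(background))) {
    abort("non-finite feature values", class = "nc_fitting_error")
  }
  J <- ncol(background)
  if (is.null(beta)) {
    cls <- if (!is.null(features)) features$defs$class else rep("linear", J)
    s <- pmax(apply(presences, 2, sd), 0.05)
    if (m == 1) s <- rep(0.05, J)
    beta <- beta_scale * beta_default(cls, m) * s / sqrt(m)
  }
  beta <- pmax(rep_len(beta, J), 1e-6)

  fbar <- colMeans(presences)
  lambda <- numeric(J)
  eta <- numeric(n)               # background linear predictor
  eta_p <- numeric(m)
  lz <- log(n)                    # log sum exp(eta)
  objective <- function(lz, mean_eta_p, lambda) {
    -mean_eta_p + lz + sum(beta * abs(lambda))
  }
  obj <- objective(lz, 0, lambda)
  obj_trace <- obj
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    obj_start <- obj
    w <- exp(eta - lz)            # fitted background distribution q
    for (j in seq_len(J)) {
      fj <- background[, j]
      mu <- sum(w * fj)
      h <- sum(w * fj^2) - mu^2
      if (h < 1e-12) next
      g <- mu - fbar[j]
      z <- lambda[j] * h - g
      lam_new <- sign(z) * max(abs(z) - beta[j], 0) / h
      d <- lam_new - lambda[j]
      if (abs(d) < 1e-14) next
      # backtrack on the exact objective (the quadratic step can overshoot)
      for (half in 1:30) {
        cand <- lambda[j] + d
        eta_new <- eta + d * fj
        lz_new <- log_sum_exp(eta_new)
        eta_p_new <- eta_p + d * presences[, j]
        lam_try <- lambda; lam_try[j] <- cand
        obj_new <- objective(lz_new, mean(eta_p_new), lam_try)
        if (obj_new <= obj + 1e-12) break
        d <- d / 2
        obj_new <- NA_real_
      }
      if (is.na(obj_new)) next
      lambda[j] <- lambda[j] + d
      eta <- eta_new; eta_p <- eta_p_new; lz <- lz_new; obj <- obj_new
      w <- exp(eta - lz)
    }
    obj_trace <- c(obj_trace, obj)
    if (abs(obj_start - obj) < convergence) { converged <- TRUE; break }
  }
  q <- exp(eta - lz)
  H <- -sum(q * log(pmax(q, 1e-300)))
  structure(
    list(features = features, lambda = setNames(lambda, colnames(background)),
         beta = beta, log_partition = lz, entropy = H,
         n_presence = m, n_background = n,
         iterations = it, objective = obj, objective_trace = obj_trace,
         converged = converged),
    class = "nc_maxent"
  )
}

#' @export
print.nc_maxent <- function(x, ...) {
  cat("<nc_maxent>", length(x$lambda), "features,",
      sum(x$lambda != 0), "active |", x$n_presence, "presences,",
      x$n_background, "background |", x$iterations, "sweeps",
      if (x$converged) "(converged)" else "(max_iter reached)",
      "| objective", format(x$objective, digits = 6), "\n")
  invisible(x)
}

# The penalized maxent objective for given coefficients, used by tests and
# by the fit itself.
maxent_objective <- function(lambda, presences, background, beta) {
  eta <- as.vector(background %*% lambda)
  -mean(as.vector(presences %*% lambda)) + log_sum_exp(eta) +
    sum(beta * abs(lambda))
}

#' Sample background cells from the calibration mask
#'
#' The background is all calibration-mask cells, uniformly subsampled
#' (without replacement) when they exceed `max_cells`.
#'
#' @param env an [env_stack()].
#' @param max_cells background cap (default 10000).
#' @param seed integer seed for the subsample.
#' @return Integer vector of cell indices into the grid.
#' @export
background_cells <- function(env, max_cells = 10000, seed = 1L) {
  cells <- which(env$calibration)
  if (length(cells) > max_cells) {
    cells <- with_seed(seed, sort(sample(cells, max_cells)))
  }
  cells
}

#' Fit a niche model to occurrence records on a stack
#'
#' Convenience wrapper tying the pieces together: locates the presence
#' cells, builds the feature set (hinge features iff more than 15
#' presences), samples the background from the calibration mask, and fits
#' the penalized model.
#'
#' @param occ occurrence tibble with `x`, `y` in km.
#' @param env an [env_stack()].
#' @param layers layers to use (default all).
#' @param hinge_knot_count,beta_scale,convergence,max_iter,background_size
#'   passed through to [build_features()], [fit_maxent()] and
#'   [background_cells()].
#' @param seed seed for the background subsample.
#' @return An `nc_maxent` model carrying its background cell indices.
#' @export
fit_species_model <- function(occ, env, layers = NULL, hinge_knot_count = 5,
                              beta_scale = 1, convergence = 1e-6,
                              max_iter = 500, background_size = 10000,
                              seed = 1L) {
  stopifnot(inherits(env, "nc_env_stack"))
  if (!is.null(layers)) {
    env <- env_stack(env$layers[layers], env$cell_km, env$period,
                     env$region, env$calibration)
  }
  fs <- build_features(env, presence_count = nrow(occ),
                       hinge_knot_count = hinge_knot_count)
  bg_cells <- background_cells(env, max_cells = background_size, seed = seed)
  d <- dim(env)
  pc <- xy_to_cell(occ$x, occ$y, d[1], d[2], env$cell_km)
  p_cells <- cbind(pc$row, pc$col)
  p_idx <- (p_cells[, 2] - 1L) * d[1] + p_cells[, 1]
  Fp <- feature_matrix(fs, stack_values(env, p_idx))
  Fb <- feature_matrix(fs, stack_values(env, bg_cells))
  model <- fit_maxent(Fp, Fb, features = fs, beta_scale = beta_scale,
                      convergence = convergence, max_iter = max_iter)
  model$background <- bg_cells
  model$presence_cells <- p_idx
  model
}

#' Project a fitted model onto an environmental stack
#'
#' Evaluates the model over every cell of `env`. The raw output is
#' `exp(lambda . f(x))` normalized by the training background partition
#' value, so projecting onto the calibration stack reproduces a
#' distribution summing to 1 over the background. The logistic output is
#' `e^H q(x) / (1 + e^H q(x))` with `H` the entropy of the fitted
#' background distribution — the conventional 0-to-1 suitability scale on
#' which a featureless model scores 0.5 everywhere. With `clamp = TRUE`
#' (default) feature values outside the training range are truncated to it
#' and the affected cells flagged in the clamping grid.
#'
#' @param model an `nc_maxent` from [fit_maxent()] or
#'   [fit_species_model()].
#' @param env an [env_stack()] containing every layer of the model.
#' @param clamp truncate out-of-range features to the training range?
#' @return An object of class `nc_suitability`: `logistic` and `raw` grids,
#'   a logical `clamped` grid, the period and the grid metadata.
#' @export
project <- function(model, env, clamp = TRUE) {
  stopifnot(inherits(model, "nc_maxent"), inherits(env, "nc_env_stack"))
  if (is.null(model$features)) {
    abort("model carries no feature set; fit via fit_species_model()",
          class = "nc_projection_error")
  }
  missing <- setdiff(model$features$layers, env_layer_names(env))
  if (length(missing) > 0) {
    abort(paste("stack lacks model layer(s):",
                paste(missing, collapse = ", ")),
          class = "nc_projection_error")
  }
  d <- dim(env)
  all_cells <- seq_len(d[1] * d[2])
  vals <- stack_values(env, all_cells, layers = model$features$layers)
  F <- feature_matrix(model$features, vals, clamp = clamp)
  eta <- as.vector(F %*% model$lambda)
  raw <- exp(eta - model$log_partition)
  eH <- exp(model$entropy)
  logistic <- eH * raw / (1 + eH * raw)
  to_grid <- function(v) matrix(v, d[1], d[2])
  structure(
    list(logistic = to_grid(logistic), raw = to_grid(raw),
         clamped = to_grid(attr(F, "clamped") %||% rep(FALSE, length(eta))),
         period = env$period, cell_km = env$cell_km, region = env$region),
    class = "nc_suitability"
  )
}

#' @export
print.nc_suitability <- function(x, ...) {
  cat("<nc_suitability> period:", x$period, "| logistic range",
      format(range(x$logistic), digits = 3), "|",
      sum(x$clamped), "clamped cells\n")
  invisible(x)
}

#' Serialize a fitted model to JSON
#'
#' Writes feature definitions, coefficients, normalizers, the entropy and
#' fit metadata to a JSON document; `read_maxent_json()` restores a model
#' that projects identically.
#'
#' @param model an `nc_maxent`.
#' @param path file path.
#' @return `write_maxent_json()` returns `path` invisibly;
#'   `read_maxent_json()` returns an `nc_maxent`.
#' @export
write_maxent_json <- function(model, path) {
  doc <- list(
    features = model$features$defs,
    layers = model$features$layers,
    lambda = as.list(model$lambda),
    beta = model$beta,
    log_partition = model$log_partition,
    entropy = model$entropy,
    metadata = list(n_presence = model$n_presence,
                    n_background = model$n_background,
                    iterations = model$iterations,
                    objective = model$objective,
                    converged = model$converged)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_maxent_json
#' @export
read_maxent_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  fs <- structure(list(defs = tibble::as_tibble(doc$features),
                       layers = doc$layers),
                  class = "nc_feature_set")
  structure(
    list(features = fs, lambda = unlist(doc$lambda), beta = doc$beta,
         log_partition = doc$log_partition, entropy = doc$entropy,
         n_presence = doc$metadata$n_presence,
         n_background = doc$metadata$n_background,
         iterations = doc$metadata$iterations,
         objective = doc$metadata$objective,
         converged = doc$metadata$converged),
    class = "nc_maxent"
  )
}
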
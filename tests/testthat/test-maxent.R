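# tiny helper: stack from explicit layer matrices, whole grid = background
stack_of <- function(..., cell_km = 10) {
  env_stack(list(...), cell_km = cell_km)
}

test_that("hinge features require strictly more than 15 presences", {
  env <- stack_of(bio1 = matrix(rnorm(100), 10), bio2 = matrix(rnorm(100), 10))
  fs15 <- build_features(env, presence_count = 15, hinge_knot_count = 5)
  expect_false(any(fs15$defs$class == "hinge"))
  expect_equal(nrow(fs15$defs), 4)  # linear + quadratic per layer

  fs16 <- build_features(env, presence_count = 16, hinge_knot_count = 5)
  expect_equal(nrow(fs16$defs), 2 * 2 + 2 * 2 * 5)
  expect_equal(sum(fs16$defs$class == "hinge"), 20)
})

test_that("constant layers are dropped with a warning", {
  env <- stack_of(bio1 = matrix(rnorm(100), 10), flat = matrix(7, 10, 10))
  expect_warning(fs <- build_features(env, presence_count = 20),
                 class = "nc_constant_layer_warning")
  expect_false("flat" %in% fs$layers)
})

test_that("features are min-max normalized to [0, 1] on the background", {
  env <- stack_of(bio1 = matrix(runif(100, -50, 30), 10))
  fs <- build_features(env, presence_count = 30)
  F <- nichecast:::feature_matrix(fs, nichecast:::stack_values(env, 1:100))
  expect_true(all(F >= 0 & F <= 1))
  expect_equal(min(F[, 1]), 0)
  expect_equal(max(F[, 1]), 1)
})

test_that("matched presence and background feature means keep lambda at 0", {
  F <- matrix(runif(200), 50, 4)
  fit <- fit_maxent(F, F, beta = rep(0.01, 4))
  expect_equal(unname(fit$lambda), rep(0, 4))
  expect_true(fit$converged)
})

test_that("a 1-feature fit matches a dense grid-search oracle", {
  # 5-cell background with one linear feature; presences concentrate on the
  # high-feature cell
  bg <- matrix(c(0, 0.25, 0.5, 0.75, 1), ncol = 1)
  pres <- matrix(rep(1, 8), ncol = 1)
  beta <- 0.05
  fit <- fit_maxent(pres, bg, beta = beta)
  grid <- seq(-2, 12, by = 1e-3)
  obj <- vapply(grid, function(l) {
    nichecast:::maxent_objective(l, pres, bg, beta)
  }, numeric(1))
  oracle_obj <- min(obj)
  expect_lt(fit$objective - oracle_obj, 1e-4)
})

test_that("a 2-cell toy matches the closed-form penalized optimum", {
  # background features {0, 1}; mean presence feature 0.8; penalty 0.1.
  # The stationarity condition sigmoid(lambda) = pbar - beta gives
  # lambda* = logit(0.7).
  bg <- matrix(c(0, 1), ncol = 1)
  pres <- matrix(c(rep(1, 4), 0), ncol = 1)  # pbar = 0.8
  fit <- fit_maxent(pres, bg, beta = 0.1, convergence = 1e-12)
  expect_equal(unname(fit$lambda), qlogis(0.7), tolerance = 1e-4)
})

test_that("doubling every penalty never increases the L1 norm of lambda", {
  set.seed(21)
  bg <- matrix(runif(600), 150, 4)
  pres <- matrix(pmin(1, runif(120) + 0.3), 30, 4)
  f1 <- fit_maxent(pres, bg, beta = rep(0.02, 4))
  f2 <- fit_maxent(pres, bg, beta = rep(0.04, 4))
  expect_lte(sum(abs(f2$lambda)), sum(abs(f1$lambda)) + 1e-10)
})

test_that("the objective is non-increasing across optimizer sweeps", {
  set.seed(22)
  bg <- matrix(runif(1000), 200, 5)
  pres <- matrix(pmin(1, runif(150)^0.5), 30, 5)
  fit <- fit_maxent(pres, bg, beta = rep(0.01, 5))
  expect_true(all(diff(fit$objective_trace) <= 1e-12))
})

test_that("projection onto the calibration stack sums raw output to 1", {
  w <- fitted_toy()
  expect_equal(sum(w$map_cur$raw[w$model$background]), 1, tolerance = 1e-10)
  expect_true(all(w$map_cur$logistic > 0 & w$map_cur$logistic < 1))
})

test_that("a null model projects uniform raw and 0.5 logistic output", {
  env <- stack_of(bio1 = matrix(runif(100), 10))
  fs <- build_features(env, presence_count = 20)
  F <- nichecast:::feature_matrix(fs, nichecast:::stack_values(env, 1:100))
  fit <- fit_maxent(F[1:10, ], F, features = fs, beta = rep(10, ncol(F)))
  expect_equal(unname(fit$lambda), rep(0, ncol(F)))  # huge penalty: null fit
  map <- project(fit, env)
  expect_equal(as.vector(map$raw), rep(1 / 100, 100))
  expect_equal(as.vector(map$logistic), rep(0.5, 100))
})

test_that("suitability is invariant to positive affine rescaling of a layer", {
  w <- fitted_toy()
  env <- w$cur
  for (nm in names(env$layers)) {
    scaled <- env
    scaled$layers[[nm]] <- 2.5 * env$layers[[nm]] - 7
    occ <- w$occ
    m1 <- fit_species_model(occ, env, background_size = 400, seed = 5,
                            max_iter = 100)
    m2 <- fit_species_model(occ, scaled, background_size = 400, seed = 5,
                            max_iter = 100)
    expect_equal(project(m2, scaled)$logistic, project(m1, env)$logistic,
                 tolerance = 1e-8)
  }
})

test_that("clamped projection truncates and flags out-of-range cells", {
  env <- stack_of(bio1 = matrix(seq(0, 1, length.out = 100), 10))
  fs <- build_features(env, presence_count = 10)
  pres <- nichecast:::feature_matrix(
    fs, nichecast:::stack_values(env, 91:100))
  bgF <- nichecast:::feature_matrix(fs, nichecast:::stack_values(env, 1:100))
  fit <- fit_maxent(pres, bgF, features = fs)
  shifted <- stack_of(bio1 = env$layers$bio1 + 0.5)  # half the cells overflow
  map <- project(fit, shifted, clamp = TRUE)
  over <- sum(shifted$layers$bio1 > max(env$layers$bio1))
  expect_equal(sum(map$clamped), over)
  # clamped features sit at the boundary: suitability equals the max-input one
  top <- which(shifted$layers$bio1 >= max(env$layers$bio1))
  expect_equal(length(unique(round(map$logistic[top], 12))), 1)
})

test_that("missing projection layers raise a projection error", {
  w <- fitted_toy()
  env <- w$cur
  env$layers$bio1 <- NULL
  expect_error(project(w$model, env), class = "nc_projection_error")
})

test_that("model JSON round-trip reproduces the projection", {
  w <- fitted_toy()
  path <- withr::local_tempfile(fileext = ".json")
  write_maxent_json(w$model, path)
  back <- read_maxent_json(path)
  expect_equal(project(back, w$cur)$logistic, w$map_cur$logistic)
})

test_that("fitting errors are raised for degenerate inputs", {
  bg <- matrix(runif(40), 20, 2)
  expect_error(fit_maxent(matrix(numeric(0), 0, 2), bg),
               class = "nc_fitting_error")
  expect_error(fit_maxent(matrix(runif(4), 2, 2), bg[1, , drop = FALSE]),
               class = "nc_fitting_error")
  expect_error(fit_maxent(matrix(runif(6), 2, 3), bg),
               class = "nc_fitting_error")
  bad <- bg; bad[1, 1] <- NaN
  expect_error(fit_maxent(matrix(runif(4), 2, 2), bad),
               class = "nc_fitting_error")
})

test_that("tidy() and glance() expose coefficients and fit metadata", {
  w <- fitted_toy()
  td <- tidy(w$model)
  expect_equal(nrow(td), length(w$model$lambda))
  expect_true(all(c("term", "layer", "class", "estimate", "penalty",
                    "active") %in% names(td)))
  gl <- glance(w$model)
  expect_equal(gl$n_presence, w$model$n_presence)
  expect_equal(gl$n_active, sum(w$model$lambda != 0))
})
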
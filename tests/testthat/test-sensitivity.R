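test_that("the known informative layer wins the single-variable ranking", {
  cfg <- small_config(seed = 51)
  env <- generate_env_stack(cfg, "current")
  sp <- thermal_species(optimum = 2, breadth = 0.5)  # responds to bio1 only
  occ <- sample_occurrences(sp, env, n = 150, seed = 52)
  tv <- top_variable(occ, env, background_size = 600, max_iter = 100)
  expect_equal(tv$variable, "bio1")
  expect_false(tv$degenerate)
})

test_that("exact AUC ties break to the first layer in name order", {
  cfg <- small_config(seed = 53)
  env <- generate_env_stack(cfg, "current")
  # duplicate bio1 under two names: identical AUCs by construction
  env2 <- env_stack(list(aaa = env$layers$bio1, bbb = env$layers$bio1),
                    env$cell_km, region = env$region,
                    calibration = env$calibration)
  sp <- thermal_species(breadth = 0.5)
  occ <- sample_occurrences(sp, env, n = 100, seed = 54)
  tv <- top_variable(occ, env2, background_size = 400, max_iter = 60)
  expect_equal(tv$variable, "aaa")
})

test_that("doubling the delta leaves other layers untouched", {
  cfg <- small_config(seed = 55)
  cur <- generate_env_stack(cfg, "current")
  fut <- generate_env_stack(cfg, "future")
  dd <- doubled_delta_stack(cur, fut, "bio2")
  expect_equal(dd$layers$bio2,
               cur$layers$bio2 + 2 * (fut$layers$bio2 - cur$layers$bio2))
  expect_equal(dd$layers$bio1, fut$layers$bio1)
  expect_equal(dd$period, "future-doubled")

  # null delta: doubling changes nothing
  same <- doubled_delta_stack(cur, cur, "bio1")
  expect_equal(same$layers, cur$layers)

  zero <- cur; one <- cur
  zero$layers$bio1 <- matrix(0, cfg$nrow, cfg$ncol)
  one$layers$bio1 <- matrix(1, cfg$nrow, cfg$ncol)
  expect_equal(doubled_delta_stack(zero, one, "bio1")$layers$bio1,
               matrix(2, cfg$nrow, cfg$ncol))
  expect_error(doubled_delta_stack(cur, fut, "nope"),
               class = "nc_grid_error")
})

test_that("halving then doubling the delta is the identity", {
  cfg <- small_config(seed = 56)
  cur <- generate_env_stack(cfg, "current")
  fut <- generate_env_stack(cfg, "future")
  half <- fut
  half$layers$bio3 <- cur$layers$bio3 +
    0.5 * (fut$layers$bio3 - cur$layers$bio3)
  expect_equal(doubled_delta_stack(cur, half, "bio3")$layers$bio3,
               fut$layers$bio3)
})

test_that("severity outcomes flag extinctions and colonization failures", {
  r1 <- tibble::tibble(species = c("resident", "colonizer", "crasher"),
                       area_current = c(100, 0, 100),
                       area_future = c(110, 40, 50))
  r2 <- tibble::tibble(species = c("resident", "colonizer", "crasher"),
                       area_current = c(100, 0, 100),
                       area_future = c(0, 0, 8))
  out <- severity_outcomes(r1, r2)
  res <- out[out$species == "resident", ]
  expect_true(res$extinct)
  expect_false(res$loss_over_90)  # extinct, not merely contracting
  col <- out[out$species == "colonizer", ]
  expect_true(col$colonization_failure)
  expect_false(col$extinct)
  cr <- out[out$species == "crasher", ]
  expect_true(cr$loss_over_90)   # 100 -> 8 is a 92% loss
  expect_false(cr$extinct)
  expect_error(severity_outcomes(r1, r2[1:2, ]), class = "nc_pairing_error")
})

test_that("severity outcomes note sign reversals between 1x and 2x", {
  r1 <- tibble::tibble(species = "flip", area_current = 100,
                       area_future = 130)
  r2 <- tibble::tibble(species = "flip", area_current = 100,
                       area_future = 70)
  out <- severity_outcomes(r1, r2)
  expect_true(out$sign_reversal)
})

test_that("a monotone fitted response to a uniform positive delta grows
           with severity", {
  # a strictly monotone model (single positive linear feature) projected on
  # stacks with a uniform positive delta must gain area with severity
  cfg <- small_config(seed = 57, delta_gradient = 0)
  cur <- generate_env_stack(cfg, "current")
  fut <- generate_env_stack(cfg, "future")
  env1 <- env_stack(list(bio1 = cur$layers$bio1), cur$cell_km, "current",
                    cur$region, cur$calibration)
  sp <- species_spec("mono", list(bio1 = list(type = "logistic",
                                              midpoint = 2.5, slope = 3)))
  occ <- sample_occurrences(sp, cur, n = 120, seed = 58)
  fs <- build_features(env1, presence_count = nrow(occ))
  fs$defs <- fs$defs[fs$defs$class == "linear", , drop = FALSE]
  d <- dim(env1)
  pc <- nichecast:::xy_to_cell(occ$x, occ$y, d[1], d[2], env1$cell_km)
  p_idx <- (pc$col - 1L) * d[1] + pc$row
  Fp <- nichecast:::feature_matrix(fs, nichecast:::stack_values(env1, p_idx))
  Fb <- nichecast:::feature_matrix(
    fs, nichecast:::stack_values(env1, which(env1$calibration)))
  model <- fit_maxent(Fp, Fb, features = fs)
  expect_gt(unname(model$lambda[1]), 0)  # presences sit high on the gradient

  fut1 <- env_stack(list(bio1 = fut$layers$bio1), fut$cell_km, "future",
                    fut$region, fut$calibration)
  env2x <- doubled_delta_stack(env1, fut1, "bio1")
  map0 <- project(model, env1)
  thr <- select_threshold(score_occurrences(map0, occ),
                          map0$logistic[env1$calibration])
  areas <- vapply(list(map0, project(model, fut1), project(model, env2x)),
                  function(m) range_area(binarize(m, thr$threshold)),
                  numeric(1))
  expect_gte(areas[2], areas[1])
  expect_gte(areas[3], areas[2])
})

test_that("the severity experiment selects the driving variable and reuses
           the 1x threshold", {
  cfg <- small_config(seed = 57, delta_gradient = 0)
  cur <- generate_env_stack(cfg, "current")
  fut <- generate_env_stack(cfg, "future")
  sp <- species_spec("mono", list(bio1 = list(type = "logistic",
                                              midpoint = 2.5, slope = 3)))
  occ <- sample_occurrences(sp, cur, n = 120, seed = 58)
  res <- severity_experiment(occ, cur, fut, background_size = 500,
                             max_iter = 100)
  expect_equal(res$variable, "bio1")
  expect_true(all(is.finite(c(res$area_current, res$area_1x, res$area_2x))))
  expect_gte(res$area_1x, res$area_current)  # warming favours this species
})
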
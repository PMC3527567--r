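block_range <- function(rows, cols, nrow = 10, ncol = 10) {
  g <- matrix(FALSE, nrow, ncol)
  g[rows, cols] <- TRUE
  range_from(g)
}

test_that("stable area equals the no-dispersal intersection by definition", {
  a <- random_range(seed = 1)
  b <- random_range(seed = 2)
  expect_equal(stable_area(a, b), wcs_range(a, b))
  expect_equal(stable_area(a, a)$cells, a$cells)
  expect_equal(sum(stable_area(a, binary_range(!a$cells, 10))$cells), 0)
})

test_that("at-least-k fractions match constructed and brute-force counts", {
  area <- block_range(1:10, 1:10)
  one_pred <- block_range(1:10, 1:10)
  expect_equal(fraction_with_at_least_k(area, list(one_pred), k = 1), 100)
  expect_equal(fraction_with_at_least_k(area, list(one_pred), k = 2), 0)

  preds <- lapply(1:5, function(i) random_range(10, 10, seed = i))
  counts <- Reduce(`+`, lapply(preds, function(p) p$cells))
  expect_equal(fraction_with_at_least_k(area, preds, k = 3),
               100 * sum(counts >= 3) / 100)
  expect_error(fraction_with_at_least_k(block_range(integer(0), 1), preds),
               class = "nc_community_error")
})

test_that("overlap fractions match constructed geometries", {
  a <- block_range(1:4, 1:10)                      # 40 cells
  expect_equal(overlap_fraction(a, block_range(1:10, 1:10)), 100)
  expect_equal(overlap_fraction(a, block_range(6:10, 1:10)), 0)
  expect_equal(overlap_fraction(a, block_range(1:2, 1:10)), 50)
  expect_error(overlap_fraction(block_range(integer(0), 1), a),
               class = "nc_community_error")
})

test_that("co-occurrence fractions match the brute-force AND tally", {
  region <- block_range(1:10, 1:10)
  expect_equal(cooccurrence_fraction(region, list(region)), 100)
  empty <- block_range(integer(0), 1)
  expect_equal(cooccurrence_fraction(region, list(region, empty)), 0)

  rs <- list(random_range(10, 10, seed = 5), random_range(10, 10, seed = 6))
  expect_equal(cooccurrence_fraction(region, rs),
               100 * sum(rs[[1]]$cells & rs[[2]]$cells) / 100)
  expect_error(cooccurrence_fraction(region, list()),
               class = "nc_community_error")
})

test_that("predator-free fractions match constructed geometries", {
  prey <- block_range(1:10, 1:10)
  expect_equal(predator_free_fraction(prey, list()), 100)
  expect_equal(predator_free_fraction(prey, list(prey)), 0)
  three_quarters <- block_range(1:10, 1:7)
  extra <- block_range(8:10, 8:10)  # overlaps part of the remaining quarter
  quarter_free <- block_range(1:10, 1:5)
  expect_equal(predator_free_fraction(prey, list(block_range(1:10, 6:10))),
               50)
  expect_equal(
    predator_free_fraction(prey, list(three_quarters,
                                      block_range(1:5, 8:10),
                                      block_range(6:10, 8:10))), 0)
})

test_that("at-least-k is non-increasing in k", {
  area <- block_range(1:10, 1:10)
  preds <- lapply(1:6, function(i) random_range(10, 10, seed = i + 20))
  fr <- vapply(1:6, function(k) {
    fraction_with_at_least_k(area, preds, k = k)
  }, numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("predator-free and at-least-one fractions are complementary", {
  for (s in 1:5) {
    prey <- random_range(10, 10, p = 0.6, seed = s + 40)
    preds <- lapply(1:3, function(i) random_range(10, 10, seed = 60 + 3 * s + i))
    expect_equal(predator_free_fraction(prey, preds) +
                   fraction_with_at_least_k(prey, preds, k = 1), 100)
  }
})

test_that("community metrics are invariant to comparison-list order", {
  area <- random_range(10, 10, p = 0.7, seed = 80)
  preds <- lapply(1:4, function(i) random_range(10, 10, seed = 90 + i))
  perm <- preds[c(3, 1, 4, 2)]
  expect_equal(fraction_with_at_least_k(area, preds, 2),
               fraction_with_at_least_k(area, perm, 2))
  expect_equal(predator_free_fraction(area, preds),
               predator_free_fraction(area, perm))
  expect_equal(cooccurrence_fraction(area, preds),
               cooccurrence_fraction(area, perm))
})

test_that("community_overlap returns tidy per-metric rows", {
  prey <- block_range(1:10, 1:10)
  preds <- list(a = block_range(1:5, 1:10), b = block_range(1:3, 1:10))
  out <- community_overlap("prey", prey, preds, period = "current", k = 2)
  expect_equal(nrow(out), 2)
  expect_equal(out$value[out$metric == "fraction_with_at_least_2"], 30)
  expect_equal(out$value[out$metric == "predator_free_fraction"], 50)
})
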
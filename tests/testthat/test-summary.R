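test_that("trend tallies on the published table match the reported counts", {
  t1 <- load_table1_fixture()
  tally <- tally_trends(t1, "a2")
  expect_equal(tally$winners, 43)
  expect_equal(tally$losers, 8)
  expect_equal(tally$colonizers, 10)
  expect_equal(tally$colonizer_bats, 8)
  expect_equal(tally$winners + tally$losers + tally$colonizers +
                 tally$unchanged, tally$total)

  empty <- tally_trends(t1[0, ], "a2")
  expect_equal(empty$total, 0)
  bad <- t1; bad$trend_a2[1] <- "X"
  expect_error(tally_trends(bad, "a2"), class = "nc_schema_error")
})

test_that("tallies are invariant to row permutation", {
  t1 <- load_table1_fixture()
  shuffled <- t1[rev(seq_len(nrow(t1))), ]
  expect_equal(tally_trends(shuffled, "b2"), tally_trends(t1, "b2"))
})

test_that("loss summaries reproduce hand arithmetic", {
  losses <- c(26, 17, 21, 8, 90, 66, 50, 39)
  reports <- tibble::tibble(
    species = letters[1:8], order = "Rodentia", type = "S",
    trend_a2 = "L", ratio_full_a2 = 100 - losses, ratio_nodisp_a2 = 50
  )
  out <- loss_summary(reports, "a2", "losers-bcs")
  expect_equal(out$mean_loss, 39.625)
  expect_equal(out$se_loss, 9.806, tolerance = 1e-3)
  expect_equal(out$n, 8)
})

test_that("a single-species population is flagged with no standard error", {
  reports <- tibble::tibble(species = "a", order = "x", type = "S",
                            trend_a2 = "L", ratio_full_a2 = 80,
                            ratio_nodisp_a2 = 80)
  out <- loss_summary(reports, "a2", "losers-bcs")
  expect_equal(out$mean_loss, 20)
  expect_true(is.na(out$se_loss))
  expect_true(out$single_species)
  expect_error(loss_summary(reports[0, ], "a2", "losers-bcs"),
               class = "nc_summary_error")
})

test_that("loss summaries on the published table match the printed values", {
  t1 <- load_table1_fixture()
  expect_equal(round(loss_summary(t1, "a2", "losers-bcs")$mean_loss), 40)
  expect_equal(round(loss_summary(t1, "a2", "losers-bcs")$se_loss), 10)
  expect_equal(round(loss_summary(t1, "b2", "losers-bcs")$mean_loss), 25)
  expect_equal(round(loss_summary(t1, "b2", "losers-bcs")$se_loss), 9)
  expect_equal(round(loss_summary(t1, "a2", "noncolonizers-wcs")$mean_loss), 19)
  expect_equal(round(loss_summary(t1, "a2", "noncolonizers-wcs")$se_loss), 4)
  expect_equal(round(loss_summary(t1, "b2", "noncolonizers-wcs")$mean_loss), 16)
  expect_equal(round(loss_summary(t1, "b2", "noncolonizers-wcs")$se_loss), 2)
})

test_that("the paired scenario test uses winners in at least one scenario", {
  t1 <- load_table1_fixture()
  out <- paired_scenario_t(t1)
  expect_equal(out$n, 44)
  expect_equal(out$df, 43)

  same <- t1
  same$ratio_full_b2 <- same$ratio_full_a2
  expect_equal(paired_scenario_t(same)$t, 0)
})

test_that("the paired t matches hand arithmetic on three pairs", {
  reports <- tibble::tibble(
    species = c("a", "b", "c"), order = "x", type = "G",
    trend_a2 = "W", trend_b2 = "W",
    ratio_full_a2 = c(10, 12, 14), ratio_full_b2 = c(8, 9, 13)
  )
  out <- paired_scenario_t(reports)
  # differences {2, 3, 1}: mean 2, sd 1, t = 2 / (1 / sqrt(3))
  expect_equal(out$t, 2 * sqrt(3), tolerance = 1e-6)
  expect_equal(out$df, 2)
  expect_error(paired_scenario_t(reports[1, ]), class = "nc_summary_error")
})

test_that("the paired t is invariant to a constant shift of both columns", {
  t1 <- load_table1_fixture()
  shifted <- t1
  shifted$ratio_full_a2 <- shifted$ratio_full_a2 - 100
  shifted$ratio_full_b2 <- shifted$ratio_full_b2 - 100
  expect_equal(paired_scenario_t(shifted)$t, paired_scenario_t(t1)$t)
})

test_that("fisher exact p matches both enumeration and the stats oracle", {
  # exhaustive check over all tables with fixed small margins
  enum_p <- function(tab) {
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
    support <- max(0, k - n):min(k, m)
    probs <- dhyper(support, m, n, k)
    sum(probs[probs <= dhyper(tab[1, 1], m, n, k) * (1 + 1e-7)])
  }
  set.seed(61)
  for (i in 1:40) {
    tab <- matrix(rpois(4, 6), 2, 2)
    if (sum(tab) == 0 || sum(tab) > 60) next
    p <- fisher_exact_p(tab)
    expect_equal(p, enum_p(tab))
    expect_equal(p, fisher.test(tab)$p.value, tolerance = 1e-9)
  }
  expect_equal(fisher_exact_p(matrix(c(8, 0, 16, 27), 2, 2)),
               fisher.test(matrix(c(8, 0, 16, 27), 2, 2))$p.value,
               tolerance = 1e-9)
})

test_that("a balanced table shows no specialist-generalist association", {
  reports <- tibble::tibble(
    species = letters[1:20], order = "x",
    type = rep(c("S", "G"), each = 10),
    trend_a2 = rep(c("L", "W", "L", "W"), each = 5),
    ratio_full_a2 = 50, ratio_nodisp_a2 = 50
  )
  out <- specialist_contingency(reports, "a2")
  expect_equal(out$fisher_p, 1, tolerance = 1e-9)
  expect_equal(out$chisq, 0)
  expect_false(out$degenerate)
})

test_that("an empty margin flags the contingency as degenerate", {
  reports <- tibble::tibble(
    species = letters[1:6], order = "x", type = c("S", "S", "S", "G", "G", "G"),
    trend_a2 = "W", ratio_full_a2 = 150, ratio_nodisp_a2 = 90
  )
  out <- specialist_contingency(reports, "a2")
  expect_true(out$degenerate)
  expect_true(is.na(out$fisher_p))
})

test_that("specialists contract significantly more often in the published table", {
  t1 <- load_table1_fixture()
  out <- specialist_contingency(t1, "a2")
  expect_equal(sum(out$table), 51)           # the non-colonizers
  # every A2 loser is a habitat specialist
  expect_equal(unname(out$table["S", ]), c(8, 16))
  expect_equal(unname(out$table["G", ]), c(0, 27))
  expect_lt(out$fisher_p, 0.05)
})

test_that("the dispersal budget and strict rule behave as specified", {
  reports <- tibble::tibble(species = c("slow", "edge", "fast", "bat"),
                            order = c("Rodentia", "Rodentia", "Rodentia",
                                      "Chiroptera"),
                            shift_km = c(700, 632, 100, 1500))
  out <- dispersal_feasibility(reports)
  expect_equal(unique(out$budget_km), 632)
  expect_equal(out$infeasible, c(TRUE, FALSE, FALSE, FALSE))
  expect_true(out$exempt[out$species == "bat"])

  withna <- dplyr::mutate(reports, shift_km = replace(shift_km, 3, NA))
  expect_warning(out2 <- dispersal_feasibility(withna),
                 class = "nc_missing_shift_warning")
  expect_equal(nrow(out2), 3)
})

test_that("the published table yields the ten known infeasible dispersers", {
  t1 <- load_table1_fixture()
  out <- dispersal_feasibility(t1)
  inf <- sort(out$species[out$infeasible])
  expect_equal(inf, sort(c(
    "Cervus elaphus", "Dama dama", "Sus scrofa", "Meles meles",
    "Mustela putorius", "Lepus europaeus", "Oryctolagus cuniculus",
    "Apodemus sylvaticus", "Castor canadensis", "Muscardinus avellanarius"
  )))
  # oracle: direct per-species comparison
  manual <- t1$species[t1$order != "Chiroptera" & t1$shift_km > 632]
  expect_setequal(inf, manual)
})

test_that("summarize_reports bundles every summary on the published table", {
  t1 <- load_table1_fixture()
  out <- summarize_reports(t1)
  expect_equal(out$tallies$winners[out$tallies$scenario == "a2"], 43)
  expect_equal(out$paired_t$df, 43)
  expect_equal(sum(out$dispersal$infeasible), 10)
  expect_named(out$contingency, c("a2", "b2"))
})
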
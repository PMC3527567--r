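#' Cross-species summary statistics
#'
#' These functions consume a Table-1-schema tibble — one row per species
#' with, for each scenario `s`, columns `trend_s` (`"W"`/`"L"`/`"C"`),
#' `ratio_full_s` (100 x full-dispersal future area / current area),
#' `ratio_nodisp_s` (likewise for no dispersal), plus `order`, `type`
#' (`"S"`/`"G"`) and `shift_km`. Both the packaged fixture
#' ([load_table1_fixture()]) and pipeline output
#' ([reports_to_table1_schema()]) have this shape.
#'
#' @name summary_stats
NULL

scenario_col <- function(reports, prefix, scenario) {
  col <- paste0(prefix, "_", scenario)
  if (!col %in% names(reports)) {
    abort(paste("missing column:", col), class = "nc_schema_error")
  }
  reports[[col]]
}

#' Tally winners, losers and colonizers
#'
#' @param reports Table-1-schema tibble (see [summary_stats]).
#' @param scenario scenario suffix, e.g. `"a2"` or `"b2"`.
#' @return A one-row tibble: `winners`, `losers`, `colonizers`,
#'   `colonizer_bats` (colonizers in Chiroptera), `unchanged`, `total`.
#' @export
tally_trends <- function(reports, scenario = "a2") {
  trend <- scenario_col(reports, "trend", scenario)
  if (nrow(reports) == 0) {
    return(tibble::tibble(winners = 0L, losers = 0L, colonizers = 0L,
                          colonizer_bats = 0L, unchanged = 0L, total = 0L))
  }
  bad <- setdiff(unique(trend), c("W", "L", "C", "0"))
  if (length(bad) > 0) {
    abort(paste("unknown trend label(s):", paste(bad, collapse = ", ")),
          class = "nc_schema_error")
  }
  tibble::tibble(
    winners = sum(trend == "W"), losers = sum(trend == "L"),
    colonizers = sum(trend == "C"),
    colonizer_bats = sum(trend == "C" & reports$order == "Chiroptera"),
    unchanged = sum(trend == "0"), total = nrow(reports)
  )
}

#' Mean and standard error of range losses
#'
#' Two populations are summarised: `"losers-bcs"`, the loss
#' `100 - ratio_full` among species classified losers (range contraction
#' despite full dispersal), and `"noncolonizers-wcs"`, the loss
#' `100 - ratio_nodisp` among all non-colonizers (the cost of no
#' dispersal). The standard error is `sd / sqrt(n)` with the n-1 sample
#' standard deviation; it is `NA` (flagged) when n = 1.
#'
#' @param reports Table-1-schema tibble.
#' @param scenario scenario suffix.
#' @param population `"losers-bcs"` or `"noncolonizers-wcs"`.
#' @return A one-row tibble: `mean_loss`, `se_loss`, `n`, `single_species`.
#' @export
loss_summary <- function(reports, scenario = "a2",
                         population = c("losers-bcs", "noncolonizers-wcs")) {
  population <- match.arg(population)
  trend <- scenario_col(reports, "trend", scenario)
  loss <- if (population == "losers-bcs") {
    (100 - scenario_col(reports, "ratio_full", scenario))[trend == "L"]
  } else {
    (100 - scenario_col(reports, "ratio_nodisp", scenario))[trend != "C"]
  }
  loss <- loss[!is.na(loss)]
  if (length(loss) == 0) abort("empty population",
                               class = "nc_summary_error")
  tibble::tibble(
    mean_loss = mean(loss),
    se_loss = if (length(loss) > 1) sd(loss) / sqrt(length(loss)) else NA_real_,
    n = length(loss), single_species = length(loss) == 1
  )
}

#' Paired t-test of full-dispersal ratios between two scenarios
#'
#' Compares the full-dispersal range ratio between scenarios over the
#' species classified winners in at least one of the two (the subset on
#' which "range expansion" is defined in both columns), by a paired
#' two-sided t-test.
#'
#' @param reports Table-1-schema tibble with both scenarios.
#' @param scenarios character vector of two scenario suffixes.
#' @return A one-row tibble: `t`, `df`, `p`, `n`, scenario means.
#' @export
paired_scenario_t <- function(reports, scenarios = c("a2", "b2")) {
  stopifnot(length(scenarios) == 2)
  t1 <- scenario_col(reports, "trend", scenarios[1])
  t2 <- scenario_col(reports, "trend", scenarios[2])
  keep <- t1 == "W" | t2 == "W"
  x <- scenario_col(reports, "ratio_full", scenarios[1])[keep]
  y <- scenario_col(reports, "ratio_full", scenarios[2])[keep]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) abort("need at least 2 paired species",
                           class = "nc_summary_error")
  if (sd(x - y) == 0) {
    # zero-variance differences: no evidence of a scenario effect
    return(tibble::tibble(t = if (mean(x - y) == 0) 0 else Inf * sign(mean(x - y)),
                          df = length(x) - 1,
                          p = if (mean(x - y) == 0) 1 else 0,
                          n = length(x), mean_1 = mean(x), mean_2 = mean(y)))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  tibble::tibble(
    t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
    n = length(x), mean_1 = mean(x), mean_2 = mean(y)
  )
}

#' Fisher exact p-value of a 2x2 table by hypergeometric summation
#'
#' Two-sided exact test: with margins fixed, sums the hypergeometric
#' probabilities of every table as or less probable than the observed one.
#'
#' @param tab 2x2 integer matrix.
#' @return p-value in (0, 1\].
#' @export
fisher_exact_p <- function(tab) {
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Specialist-versus-generalist contingency analysis
#'
#' Crosses habitat-breadth type (`S`/`G`) with loser/winner status over the
#' non-colonizer species of one scenario and tests the association two
#' ways: the Fisher exact p (by [fisher_exact_p()]) and the Pearson
#' chi-squared statistic without continuity correction. Both are reported
#' because published practice sometimes labels a chi-squared statistic as a
#' Fisher test.
#'
#' @param reports Table-1-schema tibble.
#' @param scenario scenario suffix.
#' @return A list: `table` (2x2, rows S/G, columns L/W), `fisher_p`,
#'   `chisq`, `chisq_df`, `chisq_p`, `degenerate` (an empty margin).
#' @export
specialist_contingency <- function(reports, scenario = "a2") {
  trend <- scenario_col(reports, "trend", scenario)
  keep <- trend %in% c("L", "W") & reports$type %in% c("S", "G")
  type <- factor(reports$type[keep], levels = c("S", "G"))
  outcome <- factor(trend[keep], levels = c("L", "W"))
  tab <- table(type, outcome)
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (degenerate) {
    return(list(table = tab, fisher_p = NA_real_, chisq = NA_real_,
                chisq_df = 1L, chisq_p = NA_real_, degenerate = TRUE))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(table = tab, fisher_p = fisher_exact_p(unclass(tab)),
       chisq = unname(ct$statistic), chisq_df = unname(ct$parameter),
       chisq_p = ct$p.value, degenerate = FALSE)
}

#' Screen range shifts against a dispersal budget
#'
#' Non-volant species whose predicted centroid shift exceeds the distance
#' reachable at `rate_km_per_yr` over `horizon_yr` (default 7.9 km/yr for
#' 80 years = 632 km, an upper dispersal rate estimated from two highly
#' invasive mammals) are flagged as unable to track their niche; bats
#' (Chiroptera) are exempt. The rule is strict: a shift exactly equal to
#' the budget is feasible.
#'
#' @param reports Table-1-schema tibble with `shift_km` and `order`.
#' @param rate_km_per_yr maximum dispersal rate (km per year).
#' @param horizon_yr projection horizon (years).
#' @return A tibble: `species`, `order`, `shift_km`, `budget_km`, `exempt`
#'   (volant), `infeasible`. Species without a shift are skipped with a
#'   warning.
#' @export
dispersal_feasibility <- function(reports, rate_km_per_yr = 7.9,
                                  horizon_yr = 80) {
  budget <- rate_km_per_yr * horizon_yr
  missing <- is.na(reports$shift_km)
  if (any(missing)) {
    warn(paste(sum(missing), "species without a shift distance skipped"),
         class = "nc_missing_shift_warning")
  }
  r <- reports[!missing, , drop = FALSE]
  tibble::tibble(
    species = r$species, order = r$order, shift_km = r$shift_km,
    budget_km = budget, exempt = r$order == "Chiroptera",
    infeasible = !(r$order == "Chiroptera") & r$shift_km > budget
  )
}

#' Full cross-species summary report
#'
#' Bundles the tallies, loss summaries, paired scenario comparison,
#' specialist contingency and dispersal screen into one list, runnable on
#' pipeline output or directly on the packaged published table.
#'
#' @param reports Table-1-schema tibble.
#' @param scenarios scenario suffixes present in `reports`.
#' @param rate_km_per_yr,horizon_yr dispersal budget parameters.
#' @return A list of tibbles (see the individual functions).
#' @export
summarize_reports <- function(reports, scenarios = c("a2", "b2"),
                              rate_km_per_yr = 7.9, horizon_yr = 80) {
  out <- list(
    tallies = dplyr::bind_rows(lapply(scenarios, function(s) {
      dplyr::mutate(tally_trends(reports, s), scenario = s, .before = 1)
    })),
    bcs_losses = dplyr::bind_rows(lapply(scenarios, function(s) {
      tryCatch(dplyr::mutate(loss_summary(reports, s, "losers-bcs"),
                             scenario = s, .before = 1),
               nc_summary_error = function(e) NULL)
    })),
    wcs_losses = dplyr::bind_rows(lapply(scenarios, function(s) {
      tryCatch(dplyr::mutate(loss_summary(reports, s, "noncolonizers-wcs"),
                             scenario = s, .before = 1),
               nc_summary_error = function(e) NULL)
    })),
    dispersal = suppressWarnings(
      dispersal_feasibility(reports, rate_km_per_yr, horizon_yr))
  )
  if (length(scenarios) == 2) {
    # not computable with fewer than two winners; omitted rather than fatal
    out$paired_t <- tryCatch(paired_scenario_t(reports, scenarios),
                             nc_summary_error = function(e) NULL)
  }
  out$contingency <- lapply(setNames(scenarios, scenarios), function(s) {
    specialist_contingency(reports, s)
  })
  out
}

#' Recast pipeline species reports into the Table-1 schema
#'
#' @param reports tibble of [species_report()] rows for one scenario.
#' @param scenario scenario suffix to append to the per-scenario columns.
#' @return A Table-1-schema tibble usable by the [summary_stats] functions.
#' @export
reports_to_table1_schema <- function(reports, scenario = "a2") {
  out <- tibble::tibble(
    species = reports$species, order = reports$order, type = reports$type,
    area_2000 = reports$area_current,
    shift_km = reports$shift_km,
    shift_bearing_deg = reports$shift_bearing_deg
  )
  out[[paste0("ratio_full_", scenario)]] <- reports$ratio_full
  out[[paste0("ratio_nodisp_", scenario)]] <- reports$ratio_nodisp
  out[[paste0("area_bcs_", scenario)]] <- reports$area_bcs
  out[[paste0("trend_", scenario)]] <- reports$trend
  out
}
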
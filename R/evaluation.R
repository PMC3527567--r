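#' Rank-based AUC for presence-background scores
#'
#' The area under the ROC curve in its rank-statistic form: the probability
#' that a randomly chosen presence outscores a randomly chosen background
#' point, with ties counting one half. With no true absences, background
#' points play the role of the negative class, as is standard for
#' presence-background evaluation.
#'
#' @param presence_scores,background_scores numeric vectors of model scores.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(presence_scores, background_scores) {
  m <- length(presence_scores); n <- length(background_scores)
  if (m == 0 || n == 0) abort("empty score vector",
                              class = "nc_evaluation_error")
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' Select the sensitivity-equals-specificity threshold
#'
#' The binarization rule: the cut-off where the difference between
#' sensitivity (fraction of presences scoring at or above the threshold)
#' and specificity (fraction of background scoring below it) is minimized.
#' Candidate thresholds are the midpoints between consecutive sorted unique
#' pooled scores plus the pooled extremes; the smallest candidate attaining
#' the minimum is returned, making the rule deterministic. When every score
#' is identical the rule is undefined and the result is flagged degenerate.
#'
#' @param presence_scores,background_scores numeric vectors of training
#'   scores.
#' @return A one-row tibble: `threshold`, `sensitivity`, `specificity`,
#'   `diff`, `degenerate`, `n_candidates`.
#' @export
select_threshold <- function(presence_scores, background_scores) {
  if (length(presence_scores) == 0 || length(background_scores) == 0) {
    abort("empty score vector", class = "nc_evaluation_error")
  }
  u <- sort(unique(c(presence_scores, background_scores)))
  if (length(u) == 1) {
    return(tibble::tibble(threshold = u, sensitivity = 1, specificity = 0,
                          diff = 1, degenerate = TRUE, n_candidates = 1L))
  }
  cand <- sort(unique(c(u[1], (head(u, -1) + tail(u, -1)) / 2,
                        u[length(u)])))
  se <- vapply(cand, function(t) mean(presence_scores >= t), numeric(1))
  sp <- vapply(cand, function(t) mean(background_scores < t), numeric(1))
  d <- abs(se - sp)
  i <- which(d <= min(d) + 1e-12)[1]
  tibble::tibble(threshold = cand[i], sensitivity = se[i],
                 specificity = sp[i], diff = d[i], degenerate = FALSE,
                 n_candidates = length(cand))
}

#' Binarize a suitability map at a threshold
#'
#' Cells whose logistic suitability is at least `tau` (and inside the
#' region mask) become suitable.
#'
#' @param map an `nc_suitability` from [project()].
#' @param tau finite threshold.
#' @return A [binary_range()].
#' @export
binarize <- function(map, tau) {
  stopifnot(inherits(map, "nc_suitability"), is.finite(tau))
  binary_range(map$logistic >= tau, map$cell_km, region = map$region)
}

#' Agreement between a predicted and a reference range
#'
#' Two percentages mirroring the published reference-range checks:
#' `pct_in_ref`, the share of the predicted range lying inside the
#' reference range, and `pct_ref_covered`, the share of the reference range
#' covered by the prediction. Either is `NA` when its denominator is empty.
#'
#' @param pred,ref [binary_range()] objects on the same grid.
#' @return A one-row tibble: `pct_in_ref`, `pct_ref_covered` (0-100).
#' @export
compare_reference_range <- function(pred, ref) {
  check_same_grid(pred, ref)
  inter <- sum(pred$cells & ref$cells)
  np <- sum(pred$cells); nr <- sum(ref$cells)
  tibble::tibble(
    pct_in_ref = if (np > 0) 100 * inter / np else NA_real_,
    pct_ref_covered = if (nr > 0) 100 * inter / nr else NA_real_
  )
}

#' Model scores at occurrence locations
#'
#' Looks up the logistic suitability of the cell each record falls in.
#'
#' @param map an `nc_suitability` from [project()].
#' @param occ occurrence tibble with `x`, `y` in km.
#' @return Numeric vector of scores, one per record.
#' @export
score_occurrences <- function(map, occ) {
  d <- dim(map$logistic)
  cells <- xy_to_cell(occ$x, occ$y, d[1], d[2], map$cell_km)
  map$logistic[cbind(cells$row, cells$col)]
}

#' Train/test accuracy report for a fitted model
#'
#' @param map an `nc_suitability` projection of the calibration stack.
#' @param train,test occurrence tibbles.
#' @param background_scores logistic scores of the background cells.
#' @return A one-row tibble with `train_auc` and `test_auc`.
#' @export
accuracy_report <- function(map, train, test, background_scores) {
  tibble::tibble(
    train_auc = auc(score_occurrences(map, train), background_scores),
    test_auc = if (nrow(test) > 0) {
      auc(score_occurrences(map, test), background_scores)
    } else NA_real_
  )
}
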
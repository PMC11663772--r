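# Post-hoc model interrogation: how often each element is selected across
# outer folds, how much it moves the hyperplane (|beta|), and how much each
# feature set contributes to an ensemble (leave-one-set-out ablation).

#' Outer-fold contribution and beta impact of feature elements
#'
#' For a nested-CV result: the percentage of outer folds in which each
#' element was selected, and its mean absolute SVM weight over the folds
#' containing it (weights are from standardized-feature space, hence
#' comparable across elements). Elements never selected get 0 for both.
#'
#' @param cv a `cv_result`.
#' @return Data frame (one row per element of the feature set) with columns
#'   `element`, `n_folds`, `contribution_pct`, `mean_abs_beta`, sorted by
#'   contribution then beta, descending.
#' @export
outer_fold_contribution <- function(cv) {
  stopifnot(inherits(cv, "cv_result"))
  p <- cv$n_elements
  nf <- length(cv$folds)
  count <- numeric(p); beta_sum <- numeric(p)
  for (f in cv$folds) {
    count[f$selected] <- count[f$selected] + 1
    beta_sum[f$selected] <- beta_sum[f$selected] + abs(f$beta)
  }
  mean_beta <- ifelse(count > 0, beta_sum / pmax(count, 1), 0)
  out <- data.frame(
    element = cv$element_names %||% sprintf("e%04d", seq_len(p)),
    n_folds = count,
    contribution_pct = 100 * count / nf,
    mean_abs_beta = mean_beta,
    stringsAsFactors = FALSE
  )
  out[order(-out$contribution_pct, -out$mean_abs_beta, out$element), ,
      drop = FALSE]
}

#' Elements ranked by mean absolute SVM weight
#'
#' The beta-impact view of [outer_fold_contribution()]: elements ordered by
#' the mean `|beta|` over the outer folds where they were selected. May
#' disagree with the occurrence-based contribution ranking; both views are
#' reported.
#'
#' @param cv a `cv_result`.
#' @return The contribution data frame sorted by `mean_abs_beta` descending.
#' @export
beta_impact <- function(cv) {
  tab <- outer_fold_contribution(cv)
  tab[order(-tab$mean_abs_beta, -tab$contribution_pct, tab$element), ,
      drop = FALSE]
}

#' Leave-one-set-out ablation of a majority-vote ensemble
#'
#' Removes each member in turn from the ensemble, refuses the remaining
#' (even-count) votes with decision-sum tie-breaking, and reports the AUC
#' drop attributable to that member. Uses the stored uni-modal predictions;
#' no model is refit. Negative drops (removal helps) are permitted.
#'
#' @param cv_map named list of `cv_result`s covering the ensemble members.
#' @param members character vector of member names (>= 3).
#' @return An `ablation_report` data frame: `removed`, `auc_reduced`,
#'   `delta_auc` (full AUC minus reduced AUC), sorted by `delta_auc`
#'   descending; attribute `full_auc`.
#' @export
ablate_ensemble <- function(cv_map, members) {
  stopifnot(length(members) >= 3L)
  full <- ensemble_performance(cv_map, members)$report$auc
  ref <- cv_map[[members[1L]]]
  negative <- setdiff(levels(ref$y), ref$positive)
  pred_map <- lapply(cv_map, function(cv) cv$predictions)
  dec_map <- lapply(cv_map, function(cv) cv$decision)
  rows <- lapply(members, function(m) {
    keep <- setdiff(members, m)
    fused <- suppressMessages(
      majority_vote(pred_map, keep, ref$positive, negative, dec_map))
    auc <- compute_metrics(fused, NULL, ref$y, ref$positive)$auc
    data.frame(removed = m, auc_reduced = auc, delta_auc = full - auc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$delta_auc, out$removed), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "full_auc") <- full
  class(out) <- c("ablation_report", class(out))
  out
}

#' Min-max normalization of contributions across models
#'
#' Normalizes outer-fold contribution percentages onto `[0, 1]` using the
#' pooled minimum and maximum over all supplied models, so contributions
#' are comparable across feature sets.
#'
#' @param tables list of contribution data frames
#'   (from [outer_fold_contribution()]).
#' @return The input tables with an added `contribution_norm` column; if
#'   all pooled contributions are equal the normalized scores are all 0 and
#'   attribute `degenerate` is set.
#' @export
normalize_contributions <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 2L)
  pooled <- unlist(lapply(tables, `[[`, "contribution_pct"))
  lo <- min(pooled); hi <- max(pooled)
  degenerate <- hi == lo
  out <- lapply(tables, function(tb) {
    tb$contribution_norm <- if (degenerate) rep(0, nrow(tb))
                            else (tb$contribution_pct - lo) / (hi - lo)
    tb
  })
  attr(out, "degenerate") <- degenerate
  out
}
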
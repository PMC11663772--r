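# Multi-modal fusion: concatenation of feature sets, forced fusion (per-set
# univariate top-5 pooling recomputed inside every training fold), and
# majority-vote ensembles over the uni-modal predictions.

#' Concatenate feature sets column-wise
#'
#' @param sets named list of feature matrices with identical subject rows
#'   (same order; checked via rownames when present, never reordered).
#' @return A `feature_set` whose element labels are prefixed by set name.
#' @export
concatenate_sets <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1L)
  if (is.null(names(sets)))
    names(sets) <- vapply(sets, function(s) attr(s, "set_name") %||% "",
                          character(1))
  ref <- rownames(sets[[1L]])
  n <- nrow(sets[[1L]])
  for (nm in names(sets)) {
    s <- sets[[nm]]
    if (nrow(s) != n) stop("subject mismatch in set '", nm, "'")
    if (!is.null(ref) && !is.null(rownames(s)) && !identical(rownames(s), ref))
      stop("subject order mismatch in set '", nm, "' (sets are never reordered)")
  }
  mats <- lapply(names(sets), function(nm) {
    m <- as.matrix(sets[[nm]])
    colnames(m) <- paste(nm, colnames(m), sep = ".")
    m
  })
  out <- do.call(cbind, mats)
  rownames(out) <- ref
  feature_set(out, paste(names(sets), collapse = "+"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Forced-fusion initial selector
#'
#' Returns a selector function for [run_nested_loocv()] over the
#' concatenation of all sets: within each training fold, the univariate
#' top-`per_set` elements of every feature set are pooled (so every set
#' contributes), and the final MRMR / CV-SVM ranking runs on the pooled
#' columns. Sets with fewer than `per_set` elements contribute all of them.
#'
#' @param set_index integer/factor vector assigning each column of the
#'   concatenated matrix to its source set.
#' @param per_set elements selected per set (default 5).
#' @return Function `(X_train, y_train) -> integer column indices`.
#' @export
forced_fusion_selector <- function(set_index, per_set = 5) {
  set_index <- as.factor(set_index)
  function(Xtr, ytr) {
    ur <- univariate_rank(Xtr, ytr, k_initial = Inf)
    pos <- match(seq_along(set_index), ur$order) # rank position per column
    unlist(lapply(levels(set_index), function(s) {
      cols <- which(set_index == s)
      cols[order(pos[cols])][seq_len(min(per_set, length(cols)))]
    }), use.names = FALSE)
  }
}

#' Nested LOOCV with forced multi-modal fusion
#'
#' Concatenates the sets and runs [run_nested_loocv()] with the
#' [forced_fusion_selector()] as the initial selection, `k_final = 5`.
#'
#' @param sets named list of feature matrices (identical subject rows).
#' @param y class labels.
#' @param per_set per-set univariate selection size.
#' @param k_final maximum number of features for the SVM.
#' @param ... passed to [run_nested_loocv()] (`method`, `positive`, ...).
#' @return A `cv_result`.
#' @export
run_forced_fusion <- function(sets, y, per_set = 5, k_final = 5, ...) {
  Xall <- concatenate_sets(sets)
  set_index <- rep(names(sets), vapply(sets, ncol, integer(1)))
  run_nested_loocv(Xall, y, k_final = k_final,
                   initial_selector = forced_fusion_selector(set_index,
                                                             per_set), ...)
}

#' Enumerate ensemble member combinations
#'
#' All unordered combinations of `n_set` feature-set names, in
#' deterministic lexicographic order of member indices.
#'
#' @param set_names character vector of available set names.
#' @param n_set ensemble size (odd; 3, 5, 7, 9 or all sets).
#' @return List of character vectors (the `EnsembleSpec`s).
#' @export
#' @examples
#' length(enumerate_ensembles(paste0("s", 1:11), 3)) # 165
enumerate_ensembles <- function(set_names, n_set) {
  stopifnot(n_set >= 1L, n_set <= length(set_names))
  if (n_set %% 2L == 0L) stop("ensemble size must be odd")
  if (anyDuplicated(set_names)) stop("set names must be unique")
  cmb <- utils::combn(set_names, n_set, simplify = FALSE)
  cmb
}

#' Majority vote over uni-modal predictions
#'
#' Per subject, the label predicted by more than half the member
#' classifiers. With an odd member count no ties arise; for even counts
#' (reachable only through ablation) the tie is broken by the sign of the
#' summed decision values (message logged).
#'
#' @param pred_map named list (or matrix columns) of per-subject label
#'   vectors, one per feature set.
#' @param members character vector of member set names.
#' @param positive positive-class label.
#' @param negative negative-class label.
#' @param dec_map optional named list of per-subject decision values, used
#'   only for even-member tie-breaking.
#' @return Factor of fused labels, levels `c(positive, negative)`.
#' @export
majority_vote <- function(pred_map, members, positive, negative,
                          dec_map = NULL) {
  stopifnot(all(members %in% names(pred_map)))
  votes <- vapply(members, function(m) as.character(pred_map[[m]]) == positive,
                  logical(length(pred_map[[members[1L]]])))
  npos <- rowSums(votes)
  nmem <- length(members)
  fused <- ifelse(npos > nmem / 2, positive, negative)
  tie <- npos == nmem / 2
  if (any(tie)) {
    if (is.null(dec_map))
      stop("even member count with ties requires decision values")
    message(sum(tie), " tie(s) broken by summed decision values")
    dsum <- rowSums(vapply(members, function(m) dec_map[[m]],
                           numeric(length(fused))))
    fused[tie] <- ifelse(dsum[tie] > 0, positive, negative)
  }
  factor(fused, levels = c(positive, negative))
}

#' Evaluate a majority-vote ensemble
#'
#' Fuses the stored uni-modal outer-fold predictions (no refit) and scores
#' the fused labels. Since fused output is binary, the reported AUC is the
#' single-point ROC value, identical to `(sensitivity + specificity) / 2`.
#'
#' @param cv_map named list of `cv_result`s, one per feature set.
#' @param members character vector of member set names.
#' @return An `ensemble_result`: list with `members`, `fused` labels and
#'   `report` (a `perf_report`).
#' @export
ensemble_performance <- function(cv_map, members) {
  stopifnot(all(members %in% names(cv_map)))
  ref <- cv_map[[members[1L]]]
  pred_map <- lapply(cv_map, function(cv) cv$predictions)
  dec_map <- lapply(cv_map, function(cv) cv$decision)
  negative <- setdiff(levels(ref$y), ref$positive)
  fused <- majority_vote(pred_map, members, ref$positive, negative, dec_map)
  structure(list(members = members, fused = fused,
                 report = compute_metrics(fused, NULL, ref$y, ref$positive)),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("<ensemble_result [%s]>\n", paste(x$members, collapse = ", ")))
  print(x$report)
  invisible(x)
}

#' Evaluate all ensembles of a given size
#'
#' @inheritParams ensemble_performance
#' @param n_set ensemble size.
#' @return Data frame with one row per combination (members, AUC and the
#'   other metrics), sorted by AUC descending.
#' @export
evaluate_ensembles <- function(cv_map, n_set) {
  specs <- enumerate_ensembles(names(cv_map), n_set)
  rows <- lapply(specs, function(m) {
    r <- ensemble_performance(cv_map, m)$report
    data.frame(members = paste(m, collapse = "+"), n_set = n_set,
               auc = r$auc, accuracy = r$accuracy, sensitivity = r$sensitivity,
               specificity = r$specificity, precision = r$precision,
               f1 = r$f1, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$auc, out$members), , drop = FALSE]
}
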
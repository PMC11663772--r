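# Linear-SVM classification with leave-one-out nested cross-validation.
# The inner LOO loop over the n-1 training subjects re-runs the full double
# feature ranking per inner fold and selects the number of features by the
# highest AUC over the pooled inner decision values; the outer model is then
# refit on all n-1 training subjects with that k. The held-out subject never
# enters ranking or standardization.

#' Fit a linear support vector machine
#'
#' C-SVC with linear kernel and fixed cost, trained by a compiled SMO
#' solver. The decision value is `x'beta + bias`, positive on the side of
#' the positive class. Features are used as given; standardization with
#' training statistics is the caller's responsibility (the nested CV does
#' this per fold).
#'
#' @param X numeric training matrix, subjects x features.
#' @param y two-class labels.
#' @param positive label of the positive class (default: first factor
#'   level), e.g. `"MDD"` for diagnosis or `"PO"` for outcome.
#' @param C cost parameter (fixed, never tuned).
#' @param eps SMO stopping tolerance.
#' @param max_iter maximum SMO pair updates.
#' @return An `svm_model`: list with `beta`, `bias`, `positive`, `levels`,
#'   `converged`.
#' @export
fit_linear_svm <- function(X, y, positive = NULL, C = 1, eps = 1e-8,
                           max_iter = 100000L) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop("training set contains a single class")
  if (nlevels(y) != 2L) stop("labels must have exactly 2 classes")
  if (is.null(positive)) positive <- levels(y)[1L]
  stopifnot(positive %in% levels(y))
  ypm <- ifelse(y == positive, 1, -1)
  fit <- smo_linear_cpp(X, ypm, C, eps, as.integer(max_iter))
  structure(list(beta = stats::setNames(fit$w, colnames(X)), bias = fit$b,
                 positive = positive, levels = levels(y),
                 converged = fit$converged),
            class = "svm_model")
}

#' Decision values of a linear SVM
#'
#' @param object an `svm_model`.
#' @param newdata numeric matrix on the model's feature columns.
#' @param ... unused.
#' @return Numeric decision values (positive side = positive class).
#' @export
predict_decision <- function(object, newdata, ...) {
  as.vector(as.matrix(newdata) %*% object$beta + object$bias)
}

#' @export
predict.svm_model <- function(object, newdata, ...) {
  dec <- predict_decision(object, newdata)
  neg <- setdiff(object$levels, object$positive)
  factor(ifelse(dec > 0, object$positive, neg), levels = object$levels)
}

#' Classification metric suite
#'
#' AUC is computed from the decision values by Mann-Whitney pair counting
#' (tied pairs count 1/2); the threshold metrics come from the predicted
#' labels. Precision and F1 are defined as 0 when their denominator is 0.
#'
#' @param pred predicted labels.
#' @param dec decision values (same length); for label-only (fused)
#'   predictions pass `NULL` and the AUC is computed from the labels, which
#'   equals `(sensitivity + specificity) / 2`.
#' @param y true labels.
#' @param positive positive-class label.
#' @return A `perf_report`: list with `auc`, `accuracy`, `sensitivity`,
#'   `specificity`, `precision`, `f1`, `n`.
#' @export
compute_metrics <- function(pred, dec, y, positive) {
  yl <- y == positive
  if (!any(yl) || all(yl)) stop("AUC undefined: one class absent")
  pl <- pred == positive
  if (is.null(dec)) dec <- ifelse(pl, 1, -1)
  tp <- sum(pl & yl); fn <- sum(!pl & yl)
  tn <- sum(!pl & !yl); fp <- sum(pl & !yl)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  prec <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  f1 <- if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
  structure(list(auc = auc_mw(dec, yl), accuracy = mean(pl == yl),
                 sensitivity = sens, specificity = spec, precision = prec,
                 f1 = f1, n = length(y), positive = positive),
            class = "perf_report")
}

#' @export
print.perf_report <- function(x, ...) {
  cat(sprintf(
    "AUC %.3f | acc %.3f | sens %.3f | spec %.3f | prec %.3f | F1 %.3f (n=%d)",
    x$auc, x$accuracy, x$sensitivity, x$specificity, x$precision, x$f1, x$n))
  if (!is.null(x$ci)) cat(sprintf(" | 95%% CI [%.3f, %.3f]", x$ci[1], x$ci[2]))
  if (!is.null(x$perm_p)) cat(sprintf(" | perm p %.3f", x$perm_p))
  cat("\n")
  invisible(x)
}

#' Nested leave-one-out cross-validation with double feature ranking
#'
#' For each outer fold (one held-out subject), an inner leave-one-out loop
#' over the remaining `n - 1` subjects re-runs the complete double ranking
#' (univariate screen then MRMR / CV-SVM) per inner fold and evaluates each
#' candidate feature count `k = 1..k_final`; the pooled inner decision
#' values give one AUC per `k`, and `k_optimal` is the smallest `k`
#' attaining the maximum. The double ranking is then recomputed on the full
#' outer training set, a linear SVM with the top `k_optimal` elements is
#' fit, and the held-out subject predicted. Features are z-scored per fit
#' with training-fold statistics.
#'
#' @param X numeric matrix, subjects x elements (one feature set, or a
#'   concatenation).
#' @param y two-class labels, length `nrow(X)`.
#' @param method final ranking method, `"mrmr"` or `"cvsvm"`.
#' @param k_initial univariate screen size (`Inf`/`"All"` = no truncation).
#' @param k_final maximum number of features entering the SVM.
#' @param positive positive-class label (default first factor level).
#' @param C SVM cost.
#' @param cvsvm_control list of arguments for [cvsvm_rank()].
#' @param initial_selector optional function `(X_train, y_train) ->`
#'   candidate column indices, replacing the univariate screen (used by
#'   forced fusion); the final ranking still runs on its output.
#' @return A `cv_result`: per-fold models (`selected`, `beta`, `bias`,
#'   `k_optimal`, `inner_auc`), pooled `predictions` and `decision` values
#'   covering each subject exactly once, and a `report` ([compute_metrics()]
#'   on the outer test predictions).
#' @export
run_nested_loocv <- function(X, y, method = c("mrmr", "cvsvm"),
                             k_initial = 10, k_final = 5, positive = NULL,
                             C = 1, cvsvm_control = list(),
                             initial_selector = NULL) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  n <- nrow(X)
  stopifnot(length(y) == n)
  if (n < 6L) stop("nested LOOCV requires at least 6 subjects")
  if (min(table(y)) < 3L) stop("each class needs at least 3 subjects")
  if (is.null(positive)) positive <- levels(y)[1L]
  method <- match.arg(method)
  neg <- setdiff(levels(y), positive)

  yl <- y == positive            # logical positive-class indicator
  ypm <- ifelse(yl, 1, -1)       # SVM target
  if (is.null(initial_selector))
    initial_selector <- function(Xtr, ytr)
      univariate_core(Xtr, ytr == positive, k_initial = k_initial)$order
  rank_cols <- function(tr_idx) {
    Xtr <- X[tr_idx, , drop = FALSE]
    init <- initial_selector(Xtr, y[tr_idx])
    Xs <- Xtr[, init, drop = FALSE]
    fr <- if (method == "mrmr") mrmr_core(Xs, yl[tr_idx])
          else cvsvm_core(Xs, yl[tr_idx], cvsvm_control)
    init[fr$order]
  }
  # train on standardized selected columns; return raw SMO fit + scaler
  fit_k <- function(tr_idx, cols, new_idx) {
    Xc <- X[tr_idx, cols, drop = FALSE]
    nr <- nrow(Xc)
    mu <- colMeans(Xc)
    sd_ <- sqrt(pmax(colSums(Xc^2) - nr * mu^2, 0) / (nr - 1))
    sd_[sd_ == 0] <- 1
    Xs <- (Xc - rep(mu, each = nr)) * rep(1 / sd_, each = nr)
    fit <- smo_linear_cpp(Xs, ypm[tr_idx], C, 1e-8, 100000L)
    dec <- sum((X[new_idx, cols] - mu) / sd_ * fit$w) + fit$b
    list(beta = stats::setNames(fit$w, colnames(X)[cols]), bias = fit$b,
         dec = dec)
  }

  decision <- numeric(n); predictions <- character(n)
  folds <- vector("list", n)
  skipped_inner <- 0L
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    kmax <- k_final
    dec_inner <- matrix(NA_real_, length(tr), kmax)
    for (jj in seq_along(tr)) {
      j <- tr[jj]
      tr2 <- tr[-jj]
      if (!any(yl[tr2]) || all(yl[tr2])) {
        skipped_inner <- skipped_inner + 1L; next
      }
      ord <- rank_cols(tr2)
      for (k in seq_len(min(kmax, length(ord)))) {
        dec_inner[jj, k] <- fit_k(tr2, ord[seq_len(k)], j)$dec
      }
    }
    inner_auc <- vapply(seq_len(kmax), function(k) {
      ok <- !is.na(dec_inner[, k])
      if (!any(ok) || length(unique(yl[tr][ok])) < 2L) return(NA_real_)
      auc_mw(dec_inner[ok, k], yl[tr][ok])
    }, numeric(1))
    k_opt <- if (all(is.na(inner_auc))) 1L
             else which.max(inner_auc) # ties: smallest k with the max
    ord_full <- rank_cols(tr)
    cols <- ord_full[seq_len(min(k_opt, length(ord_full)))]
    fk <- fit_k(tr, cols, i)
    decision[i] <- fk$dec
    predictions[i] <- if (fk$dec > 0) positive else neg
    folds[[i]] <- list(test_index = i, selected = cols,
                       elements = colnames(X)[cols],
                       beta = fk$beta, bias = fk$bias,
                       k_optimal = length(cols), inner_auc = inner_auc)
  }
  predictions <- factor(predictions, levels = levels(y))
  structure(list(
    folds = folds, predictions = predictions, decision = decision,
    y = y, positive = positive, method = method, k_initial = k_initial,
    k_final = k_final, n_elements = ncol(X),
    element_names = colnames(X), skipped_inner = skipped_inner,
    report = compute_metrics(predictions, decision, y, positive)
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  ko <- vapply(x$folds, `[[`, numeric(1), "k_optimal")
  cat(sprintf("<cv_result: %d outer folds, %s ranking, mean k_optimal %.2f>\n",
              length(x$folds), x$method, mean(ko)))
  print(x$report)
  invisible(x)
}
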
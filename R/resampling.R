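# Pipeline-preserving permutation significance, bootstrap CIs for the AUC,
# and the FDR-corrected mass-univariate group screen.

#' Permutation test of a classification pipeline
#'
#' Reruns the entire classification set-up (nested cross-validation with
#' double feature selection) under `n_perm` random permutations of the
#' class labels and compares the true test AUC with the null distribution.
#' The p-value is the fraction of permutations whose AUC is greater than or
#' equal to the true AUC (ties count against the hypothesis), so it has
#' resolution `1 / n_perm` and can be exactly 0 (reported in text output as
#' `< 1/n_perm`).
#'
#' @param runner function `(X, y) -> AUC` executing the full pipeline
#'   (e.g. `function(X, y) run_nested_loocv(X, y, ...)$report$auc`); must be
#'   deterministic given its inputs.
#' @param X feature matrix.
#' @param y class labels.
#' @param n_perm number of permutations (the reference protocol uses 1000).
#' @param seed master seed; each permutation uses a derived child seed.
#' @return A `permutation_report`: list with `true_auc`, `null_auc`
#'   (length `n_perm`), `p`, `n_perm`, `seed`.
#' @export
permutation_test <- function(runner, X, y, n_perm = 1000, seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be at least 1")
  true_auc <- runner(X, y)
  null_auc <- vapply(seq_len(n_perm), function(b) {
    set.seed(child_seed(seed, "perm", b))
    runner(X, sample(y))
  }, numeric(1))
  structure(list(true_auc = true_auc, null_auc = null_auc,
                 p = mean(null_auc >= true_auc), n_perm = n_perm,
                 seed = seed),
            class = "permutation_report")
}

#' @export
print.permutation_report <- function(x, ...) {
  ptxt <- if (x$p == 0) sprintf("< %g", 1 / x$n_perm) else sprintf("%.4g", x$p)
  cat(sprintf("<permutation_report: true AUC %.3f, p %s (%d permutations)>\n",
              x$true_auc, ptxt, x$n_perm))
  invisible(x)
}

#' Bootstrap percentile confidence interval for the AUC
#'
#' Resamples (decision value, label) pairs with replacement to the original
#' sample size (predictions fixed, no refitting), computes the AUC per
#' resample and returns the percentile interval. Resamples missing a class
#' are redrawn (count recorded).
#'
#' @param dec decision values (or predicted scores/labels as numbers).
#' @param y class labels.
#' @param positive positive-class label.
#' @param n_boot number of bootstrap resamples.
#' @param seed master seed; replicates use derived child seeds.
#' @param level confidence level.
#' @return A `bootstrap_report`: list with `auc` (point estimate), `ci`,
#'   `samples`, `n_boot`, `redrawn`.
#' @export
bootstrap_auc_ci <- function(dec, y, positive, n_boot = 1000, seed = 1L,
                             level = 0.95) {
  yl <- y == positive
  if (sum(yl) < 2L || sum(!yl) < 2L) stop("CI unavailable: need >= 2 per class")
  n <- length(dec)
  redrawn <- 0L
  samples <- vapply(seq_len(n_boot), function(b) {
    set.seed(child_seed(seed, "boot", b))
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(yl[idx])) == 2L) break
      redrawn <<- redrawn + 1L
    }
    auc_mw(dec[idx], yl[idx])
  }, numeric(1))
  qs <- stats::quantile(samples, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  structure(list(auc = auc_mw(dec, yl), ci = qs, samples = samples,
                 n_boot = n_boot, level = level, redrawn = redrawn,
                 seed = seed),
            class = "bootstrap_report")
}

#' @export
print.bootstrap_report <- function(x, ...) {
  cat(sprintf("<bootstrap_report: AUC %.3f, %g%% CI [%.3f, %.3f] (%d resamples)>\n",
              x$auc, 100 * x$level, x$ci[1], x$ci[2], x$n_boot))
  invisible(x)
}

#' Mass-univariate group-difference screen with FDR correction
#'
#' For every element of every feature set, computes the group difference
#' with the same normality-gated test as the univariate ranking (two-sample
#' t-test if both classes pass Shapiro-Wilk at `alpha`, Wilcoxon rank-sum
#' otherwise) and applies Benjamini-Hochberg FDR correction at `alpha`
#' within each feature set separately.
#'
#' @param sets named list of feature matrices (same subject rows).
#' @param y class labels.
#' @param positive positive-class label (defines the direction sign).
#' @param alpha FDR level.
#' @return Data frame with columns `set`, `element`, `p`, `p_adj`,
#'   `significant`, `direction` (+1 if the positive class mean is higher),
#'   `test`.
#' @export
group_difference_screen <- function(sets, y, positive = NULL, alpha = 0.05) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  y <- droplevels(as.factor(y))
  if (min(table(y)) < 3L) stop("need at least 3 subjects per class")
  if (is.null(positive)) positive <- levels(y)[1L]
  pos <- y == positive
  out <- lapply(names(sets), function(nm) {
    Xm <- as.matrix(sets[[nm]])
    ur <- univariate_rank(Xm, y, k_initial = Inf, alpha = alpha)
    dirn <- sign(colMeans(Xm[pos, , drop = FALSE]) -
                 colMeans(Xm[!pos, , drop = FALSE]))
    p_adj <- stats::p.adjust(ur$p, method = "BH")
    data.frame(set = nm,
               element = colnames(Xm) %||% sprintf("e%04d", seq_len(ncol(Xm))),
               p = ur$p, p_adj = p_adj, significant = p_adj <= alpha,
               direction = dirn, test = ur$test,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}
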
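# Vectorised column-wise statistics used in the nested-CV hot path.
# The univariate screen is re-run for every inner fold of every outer fold
# (O(n^2) times per pipeline), so each primitive operates on all feature
# columns at once. All are validated against their stats:: counterparts in
# the test suite.

#' Shapiro-Wilk W and p-value for every column of a matrix
#'
#' Vectorised implementation of Royston's approximation to the Shapiro-Wilk
#' test (the algorithm behind [stats::shapiro.test()]), computing the weight
#' vector once per sample size and the statistic for all columns through
#' matrix operations.
#'
#' @param X numeric matrix (observations x variables), 3 <= nrow <= 5000.
#' @return A list with numeric vectors `W` and `p` (one per column). Columns
#'   with zero variance get `W = NA` and `p = 0` (treated as non-normal by
#'   the gate).
#' @export
col_shapiro <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L || n > 5000L) stop("col_shapiro requires 3 <= n <= 5000")
  a <- sw_weights(n)
  Xs <- colwise_sort(X)
  num <- as.vector(crossprod(a, Xs))^2
  cm <- colMeans(X)
  den <- colSums(X^2) - n * cm^2
  W <- num / den
  W[den <= 0 | !is.finite(W)] <- NA_real_
  p <- sw_pvalue(W, n)
  p[is.na(W)] <- 0
  list(W = W, p = p)
}

# Royston (1995) AS R94 weights for sample size n
sw_weights <- function(n) {
  m <- stats::qnorm((seq_len(n) - 3 / 8) / (n + 1 / 4))
  mm <- sum(m^2)
  c_ <- m / sqrt(mm)
  if (n == 3L) return(c(-sqrt(0.5), 0, sqrt(0.5)))
  u <- 1 / sqrt(n)
  a <- numeric(n)
  an <- c_[n] + 0.221157 * u - 0.147981 * u^2 - 2.071190 * u^3 +
    4.434685 * u^4 - 2.706056 * u^5
  if (n > 5L) {
    an1 <- c_[n - 1L] + 0.042981 * u - 0.293762 * u^2 - 1.752461 * u^3 +
      5.682633 * u^4 - 3.582633 * u^5
    phi <- (mm - 2 * m[n]^2 - 2 * m[n - 1L]^2) / (1 - 2 * an^2 - 2 * an1^2)
    a[3:(n - 2L)] <- m[3:(n - 2L)] / sqrt(phi)
    a[n] <- an; a[n - 1L] <- an1
    a[1L] <- -an; a[2L] <- -an1
  } else {
    phi <- (mm - 2 * m[n]^2) / (1 - 2 * an^2)
    a[2:(n - 1L)] <- m[2:(n - 1L)] / sqrt(phi)
    a[n] <- an; a[1L] <- -an
  }
  a
}

# Royston (1995) normalising transformation of W -> p-value
sw_pvalue <- function(W, n) {
  w1 <- 1 - W
  if (n == 3L) {
    p <- 6 / pi * (asin(sqrt(W)) - asin(sqrt(0.75)))
    return(pmin(pmax(p, 0), 1))
  }
  if (n <= 11L) {
    g <- -2.273 + 0.459 * n
    mu <- 0.5440 - 0.39978 * n + 0.025054 * n^2 - 0.0006714 * n^3
    sig <- exp(1.3822 - 0.77857 * n + 0.062767 * n^2 - 0.0020322 * n^3)
    z <- (-log(g - log(w1)) - mu) / sig
  } else {
    ln <- log(n)
    mu <- -1.5861 - 0.31082 * ln - 0.083751 * ln^2 + 0.0038915 * ln^3
    sig <- exp(-0.4803 - 0.082676 * ln + 0.0030302 * ln^2)
    z <- (log(w1) - mu) / sig
  }
  stats::pnorm(z, lower.tail = FALSE)
}

# sort every column of X with a single radix order over (column, value)
colwise_sort <- function(X) {
  n <- nrow(X); p <- ncol(X)
  cols <- rep(seq_len(p), each = n)
  matrix(as.vector(X)[order(cols, as.vector(X), method = "radix")], n, p)
}

# per-column ranks; single radix order, with stats::rank fallback on ties
colwise_rank <- function(X) {
  n <- nrow(X); p <- ncol(X)
  cols <- rep(seq_len(p), each = n)
  o <- order(cols, as.vector(X), method = "radix")
  R <- matrix(0, n, p)
  R[o] <- rep.int(seq_len(n), p)
  tied <- which(vapply(seq_len(p), function(j) anyDuplicated(X[, j]) > 0L,
                       logical(1)))
  for (j in tied) R[, j] <- rank(X[, j])
  R
}

#' Column-wise pooled-variance two-sample t-test
#'
#' @param X numeric matrix (observations x variables).
#' @param g logical vector, `TRUE` for group 1.
#' @return List with vectors `statistic` and `p` (two-sided). Zero pooled
#'   variance yields `statistic = 0`, `p = 1`.
#' @export
col_ttest <- function(X, g) {
  X <- as.matrix(X)
  n1 <- sum(g); n2 <- sum(!g)
  stopifnot(n1 >= 2L, n2 >= 2L)
  m1 <- colMeans(X[g, , drop = FALSE]); m2 <- colMeans(X[!g, , drop = FALSE])
  ss1 <- colSums(X[g, , drop = FALSE]^2) - n1 * m1^2
  ss2 <- colSums(X[!g, , drop = FALSE]^2) - n2 * m2^2
  df <- n1 + n2 - 2L
  sp2 <- (ss1 + ss2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  t[!is.finite(t)] <- 0
  p <- 2 * stats::pt(-abs(t), df)
  list(statistic = t, p = p)
}

#' Column-wise Wilcoxon rank-sum test (normal approximation)
#'
#' Matches [stats::wilcox.test()] with `exact = FALSE, correct = TRUE`,
#' including the tie correction.
#'
#' @inheritParams col_ttest
#' @return List with vectors `statistic` (the Mann-Whitney U of group 1)
#'   and `p` (two-sided).
#' @export
col_wilcox <- function(X, g) {
  X <- as.matrix(X)
  n1 <- sum(g); n2 <- sum(!g); n <- n1 + n2
  R <- colwise_rank(X)
  U <- colSums(R[g, , drop = FALSE]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  # tie correction per column (continuous data rarely has ties: cheap guard)
  ties <- vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    if (anyDuplicated(x) == 0L) return(0)
    tt <- tabulate(match(x, unique(x)))
    sum(tt^3 - tt)
  }, numeric(1))
  sig2 <- n1 * n2 / 12 * ((n + 1) - ties / (n * (n - 1)))
  z <- U - mu
  z <- sign(z) * pmax(abs(z) - 0.5, 0) / sqrt(sig2)
  z[!is.finite(z)] <- 0
  p <- 2 * stats::pnorm(-abs(z))
  list(statistic = U, p = pmin(p, 1))
}

#' Area under the ROC curve by Mann-Whitney pair counting
#'
#' Rank-based AUC over continuous or binary scores; tied pairs count 1/2,
#' so the AUC of binary fused labels equals balanced accuracy
#' `(sensitivity + specificity) / 2`.
#'
#' @param scores numeric decision values, larger = more positive.
#' @param labels logical (or coercible) vector, `TRUE` = positive class.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' auc_mw(c(0.9, 0.8, 0.4, 0.2), c(TRUE, TRUE, FALSE, TRUE))
auc_mw <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("AUC undefined: one class absent")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
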
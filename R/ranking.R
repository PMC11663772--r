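# Double feature ranking: a univariate screen gated by per-class normality
# testing selects the k_initial most group-different elements; MRMR or the
# concave-minimization SVM (CV-SVM) then produces the final ordering from
# which nested candidate prefixes of size 1..k_final are built.

#' Univariate group-difference ranking with a normality gate
#'
#' For every element, Shapiro-Wilk normality is assessed in each class at
#' `alpha`; if both classes look normal a pooled two-sample t-test is used,
#' otherwise the Wilcoxon rank-sum test. Elements are ordered by ascending
#' p-value, ties broken by descending absolute statistic, then element index.
#' With fewer than 3 observations in a class the normality gate is skipped
#' and the rank-sum test used throughout (flagged).
#'
#' @param X numeric matrix, subjects x elements (training rows only).
#' @param y class labels (two levels; factor, character or logical).
#' @param k_initial number of top elements retained; `Inf` or `"All"` keeps
#'   every element.
#' @param alpha significance level of the normality gate.
#' @return A `ranking_result`: list with `order` (column indices, best
#'   first), `p`, `statistic`, `test` (`"t"`/`"wilcoxon"` per element),
#'   `method`, `k_initial` and `gate_skipped`.
#' @export
univariate_rank <- function(X, y, k_initial = Inf, alpha = 0.05) {
  X <- as.matrix(X)
  g <- as_group1(y)
  res <- univariate_core(X, g, k_initial, alpha)
  structure(c(res, list(method = "univariate", k_initial = k_initial)),
            class = "ranking_result")
}

# hot-path core on a precomputed logical group indicator; compiled screen
univariate_core <- function(X, g, k_initial = Inf, alpha = 0.05) {
  n1 <- sum(g); n2 <- sum(!g)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 subjects per class")
  if (identical(k_initial, "All")) k_initial <- Inf
  p_el <- ncol(X)
  gate_skipped <- n1 < 3L || n2 < 3L
  if (gate_skipped) {
    a1 <- a2 <- numeric(0)
  } else {
    a1 <- sw_weights_cached(n1); a2 <- sw_weights_cached(n2)
  }
  res <- univariate_core_cpp(X, g, alpha, a1, a2, !gate_skipped)
  p <- res$p; stat <- res$statistic
  ord <- order(p, -abs(stat), seq_len(p_el))
  keep <- seq_len(min(k_initial, p_el))
  list(order = ord[keep], p = p, statistic = stat,
       test = ifelse(res$is_t, "t", "wilcoxon"),
       gate_skipped = gate_skipped)
}

# memoised Shapiro-Wilk weight vectors by sample size
.sw_cache <- new.env(parent = emptyenv())
sw_weights_cached <- function(n) {
  key <- as.character(n)
  w <- .sw_cache[[key]]
  if (is.null(w)) {
    w <- sw_weights(n)
    .sw_cache[[key]] <- w
  }
  w
}

#' @export
print.ranking_result <- function(x, ...) {
  cat(sprintf("<ranking_result (%s): %d elements, top: %s>\n", x$method,
              length(x$order), paste(utils::head(x$order, 5), collapse = ", ")))
  invisible(x)
}

as_group1 <- function(y) {
  y <- as.factor(y)
  if (nlevels(droplevels(y)) != 2L) stop("labels must have exactly 2 classes")
  y == levels(droplevels(y))[1L]
}

#' Minimum-redundancy maximum-relevance (MRMR) ranking
#'
#' Greedy forward ordering maximizing relevance to the class label minus
#' the mean redundancy with already-chosen elements. For continuous features
#' and a binary class, relevance is the one-way F statistic mapped to its
#' equivalent correlation scale, `sqrt(F / (F + n - 2))` (the point-biserial
#' correlation), and redundancy is the mean absolute Pearson correlation, so
#' both terms live on `[0, 1]` and an exact duplicate of a chosen element is
#' maximally penalised.
#'
#' @param X numeric matrix whose columns are the candidates (typically the
#'   univariate top-`k_initial` columns).
#' @param y class labels.
#' @return A `ranking_result` with `order` over columns of `X` and `score`
#'   (the greedy objective at selection time).
#' @export
mrmr_rank <- function(X, y) {
  X <- as.matrix(X)
  g <- as_group1(y)
  res <- mrmr_core(X, g)
  structure(c(res, list(method = "mrmr")), class = "ranking_result")
}

mrmr_core <- function(X, g) {
  res <- mrmr_core_cpp(X, as.numeric(g))
  list(order = res$order, score = res$score)
}

# pure-R greedy MRMR, kept as the dual route checked against the compiled
# core in the test suite
mrmr_core_r <- function(X, g) {
  p <- ncol(X)
  rel <- suppressWarnings(abs(stats::cor(X, as.numeric(g))))[, 1L]
  rel[!is.finite(rel)] <- 0 # constant columns: relevance 0
  if (p == 1L) return(list(order = 1L, score = rel))
  C <- suppressWarnings(abs(stats::cor(X)))
  C[!is.finite(C)] <- 0
  order_out <- integer(p); score <- numeric(p)
  chosen <- logical(p)
  first <- which.max(rel) # which.max breaks ties by lowest index
  order_out[1L] <- first; score[1L] <- rel[first]; chosen[first] <- TRUE
  for (step in 2L:p) {
    cand <- which(!chosen)
    red <- if (sum(chosen) == 1L) C[cand, chosen]
           else rowMeans(C[cand, chosen, drop = FALSE])
    obj <- rel[cand] - red
    best <- cand[which.max(obj)]
    order_out[step] <- best
    score[step] <- max(obj)
    chosen[best] <- TRUE
  }
  list(order = order_out, score = score)
}

#' Feature selection via concave minimization with a linear SVM (CV-SVM)
#'
#' Finds a sparse separating plane by minimizing misclassification distance
#' plus a concave penalty on the feature-use indicator, following the
#' feature-selection-via-concave-minimization program: the step function on
#' `|w|` is approximated by `1 - exp(-alpha * v)` with `|w| <= v`, and the
#' resulting program is solved by successive linearization, each step a
#' linear program. Elements are ordered by descending `|w|` of the final
#' plane; zero-weight elements are appended ordered by univariate p-value.
#'
#' @param X numeric matrix of candidate columns (training rows only).
#' @param y class labels; the first factor level is taken as class A.
#' @param alpha steepness of the exponential penalty approximation.
#' @param lambda trade-off between misclassification error (weight
#'   `1 - lambda`) and feature suppression (weight `lambda`).
#' @param max_iter maximum successive-LP iterations.
#' @param tol objective-improvement convergence tolerance.
#' @return A `ranking_result` with `order`, `weights` (the sparse plane),
#'   `bias`, `iterations`, and `flag` (`"ok"`, `"fallback"` when an LP step
#'   failed and the previous iterate was kept, or `"max_iter"`).
#' @export
cvsvm_rank <- function(X, y, alpha = 5, lambda = 0.2, max_iter = 50,
                       tol = 1e-6) {
  X <- as.matrix(X)
  g <- as_group1(y)
  d <- ncol(X)
  A <- X[g, , drop = FALSE]; B <- X[!g, , drop = FALSE]
  m <- nrow(A); k <- nrow(B)
  # LP variables: [w+ (d), w- (d), gamma+ , gamma-, y (m), z (k), v (d)]
  nv <- 2L * d + 2L + m + k + d
  iw_p <- 1:d; iw_m <- d + 1:d
  ig <- 2L * d + 1:2
  iy <- 2L * d + 2L + seq_len(m)
  iz <- 2L * d + 2L + m + seq_len(k)
  iv <- 2L * d + 2L + m + k + seq_len(d)
  # constraints (<=): -(Aw - gamma e + y) <= -e ; Bw - gamma e - z <= -e ;
  #                   w - v <= 0 ; -w - v <= 0
  Acon <- matrix(0, m + k + 2L * d, nv)
  Acon[seq_len(m), iw_p] <- -A; Acon[seq_len(m), iw_m] <- A
  Acon[seq_len(m), ig] <- c(rep(1, m)) %o% c(1, -1)
  Acon[seq_len(m), iy] <- -diag(m)
  Acon[m + seq_len(k), iw_p] <- B; Acon[m + seq_len(k), iw_m] <- -B
  Acon[m + seq_len(k), ig] <- rep(1, k) %o% c(-1, 1)
  Acon[m + seq_len(k), iz] <- -diag(k)
  rw <- m + k + seq_len(d)
  Acon[rw, iw_p] <- diag(d); Acon[rw, iw_m] <- -diag(d); Acon[rw, iv] <- -diag(d)
  rw2 <- m + k + d + seq_len(d)
  Acon[rw2, iw_p] <- -diag(d); Acon[rw2, iw_m] <- diag(d); Acon[rw2, iv] <- -diag(d)
  bcon <- c(rep(-1, m + k), rep(0, 2L * d))

  base_cost <- numeric(nv)
  base_cost[iy] <- (1 - lambda) / m
  base_cost[iz] <- (1 - lambda) / k
  solve_lp <- function(v_grad) {
    cost <- base_cost
    cost[iv] <- v_grad
    res <- lp_solve(cost, Acon, bcon)
    if (res$status != "optimal") return(NULL)
    res$x
  }
  objective <- function(w, gamma) {
    err_a <- pmax(1 - (A %*% w - gamma), 0)
    err_b <- pmax(1 + (B %*% w - gamma), 0)
    (1 - lambda) * (mean(err_a) + mean(err_b)) +
      lambda * sum(1 - exp(-alpha * abs(w)))
  }

  v_cur <- rep(0, d) # linearisation point
  w <- rep(0, d); gamma <- 0
  obj <- objective(w, gamma)
  flag <- "max_iter"; it <- 0L
  support <- function(w) which(abs(w) > 1e-8)
  while (it < max_iter) {
    it <- it + 1L
    grad <- lambda * alpha * exp(-alpha * v_cur)
    x <- solve_lp(grad)
    if (is.null(x)) { flag <- "fallback"; break }
    w_new <- x[iw_p] - x[iw_m]
    gamma_new <- x[ig[1L]] - x[ig[2L]]
    v_new <- abs(w_new)
    obj_new <- objective(w_new, gamma_new)
    same_support <- identical(support(w_new), support(w))
    improved <- obj - obj_new
    w <- w_new; gamma <- gamma_new; v_cur <- v_new
    if (same_support && improved < tol && it > 1L) { flag <- "ok"; break }
    obj <- obj_new
  }
  aw <- abs(w)
  nz <- which(aw > 1e-8)
  zero <- setdiff(seq_len(d), nz)
  up <- univariate_rank(X, y)$p
  ord <- c(nz[order(-aw[nz], nz)], zero[order(up[zero], zero)])
  structure(list(order = ord, weights = w, bias = -gamma, iterations = it,
                 flag = flag, method = "cvsvm"),
            class = "ranking_result")
}

#' Nested candidate element sets from a ranking
#'
#' Prefix chains of the final ranking: sets of size `1..min(k_final,
#' available)`, each a prefix of the previous.
#'
#' @param ranking a `ranking_result` (or integer vector of ordered indices).
#' @param k_final maximum candidate-set size.
#' @return List of integer vectors.
#' @export
#' @examples
#' incremental_candidates(c(3L, 1L, 2L), k_final = 5)
incremental_candidates <- function(ranking, k_final) {
  ord <- if (inherits(ranking, "ranking_result")) ranking$order else ranking
  if (length(ord) == 0L) stop("empty ranking")
  lapply(seq_len(min(k_final, length(ord))), function(k) ord[seq_len(k)])
}

# Double ranking: univariate screen to k_initial columns, then final
# ranking by MRMR or CV-SVM. Returns indices into the columns of X.
double_rank <- function(X, y, method = c("mrmr", "cvsvm"), k_initial = 10,
                        k_final = 5, cvsvm_control = list()) {
  method <- match.arg(method)
  ur <- univariate_rank(X, y, k_initial = k_initial)
  init <- ur$order
  Xs <- X[, init, drop = FALSE]
  fr <- if (method == "mrmr") mrmr_rank(Xs, y)
        else do.call(cvsvm_rank, c(list(X = Xs, y = y), cvsvm_control))
  init[fr$order]
}

# cvsvm core on a logical indicator (delegates; cvsvm is not hot-path)
cvsvm_core <- function(X, g, control = list()) {
  y <- factor(ifelse(g, "g1", "g2"), levels = c("g1", "g2"))
  do.call(cvsvm_rank, c(list(X = X, y = y), control))
}
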
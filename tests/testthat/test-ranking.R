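# Double feature ranking: univariate screen, MRMR, CV-SVM, prefixes.

test_that("exchangeable elements rank last, planted elements first", {
  set.seed(1)
  fx <- make_two_group(10, 10, 6, seed = 2)
  fx$X[, 6] <- rep(seq_len(10), 2) # identical samples in both groups
  r <- univariate_rank(fx$X, fx$y)
  expect_equal(r$p[6], 1)
  expect_equal(r$order[length(r$order)], 6L)
})

test_that("a planted d=3 element wins the univariate screen almost surely", {
  hits <- vapply(1:100, function(s) {
    fx <- make_two_group(20, 20, 30, d = 3, planted = 7L, seed = 1000 + s)
    univariate_rank(fx$X, fx$y)$order[1] == 7L
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("the normality gate routes heavy-tailed data to the rank-sum test", {
  set.seed(3)
  n <- 15
  X <- cbind(rnorm(2 * n), c(rcauchy(n) * 100, rcauchy(n) * 100 + 3))
  y <- factor(rep(c("A", "B"), each = n))
  r <- univariate_rank(X, y)
  expect_equal(r$test[2], "wilcoxon")
  expect_equal(r$test[1], "t")
})

test_that("gate is skipped with fewer than 3 per class", {
  fx <- make_two_group(2, 4, 3, seed = 4)
  r <- univariate_rank(fx$X, fx$y)
  expect_true(r$gate_skipped)
  expect_true(all(r$test == "wilcoxon"))
})

test_that("k_initial truncates and 'All' keeps everything", {
  fx <- make_two_group(8, 8, 12, seed = 5)
  expect_length(univariate_rank(fx$X, fx$y, k_initial = 5)$order, 5L)
  expect_length(univariate_rank(fx$X, fx$y, k_initial = "All")$order, 12L)
})

test_that("MRMR never ranks an exact duplicate second", {
  for (s in 1:10) {
    set.seed(s)
    n <- 30
    f <- c(rnorm(n / 2, 1.5), rnorm(n / 2, -1.5))
    X <- cbind(f, f, matrix(rnorm(n * 3), n, 3))
    y <- factor(rep(c("A", "B"), each = n / 2))
    r <- mrmr_rank(X, y)
    expect_true(r$order[1] %in% c(1L, 2L))
    expect_false(r$order[2] %in% c(1L, 2L))
  }
})

test_that("MRMR with a single candidate returns it", {
  fx <- make_two_group(6, 6, 1, seed = 6)
  expect_equal(mrmr_rank(fx$X, fx$y)$order, 1L)
})

test_that("MRMR matches an independently coded greedy oracle", {
  set.seed(7)
  for (rep in 1:20) {
    n <- 24
    X <- matrix(rnorm(n * 6), n, 6)
    X[, 2] <- X[, 1] * 0.9 + rnorm(n, 0, 0.3)
    y <- factor(rep(c("A", "B"), each = n / 2))
    X[y == "A", 1] <- X[y == "A", 1] + 1
    r <- mrmr_rank(X, y)
    expect_equal(as.integer(r$order),
                 as.integer(mrmr_oracle(X, as.numeric(y == "A"))))
  }
})

test_that("CV-SVM finds the sparse separating dimension", {
  set.seed(8)
  n <- 30
  X <- cbind(c(rnorm(n / 2, 2), rnorm(n / 2, -2)), rnorm(n))
  y <- factor(rep(c("A", "B"), each = n / 2))
  r <- cvsvm_rank(X, y)
  expect_equal(r$order[1], 1L)
  expect_lt(abs(r$weights[2]), 1e-6)
  expect_gt(abs(r$weights[1]), 0.1)
})

test_that("CV-SVM ranks the best single-feature dimension first (enumeration)", {
  # exhaustive single-feature linear-SVM enumeration as the oracle
  set.seed(9)
  for (rep in 1:5) {
    n <- 24
    d_true <- sample(1:4, 1)
    X <- matrix(rnorm(n * 4), n, 4)
    y <- factor(rep(c("A", "B"), each = n / 2))
    X[y == "A", d_true] <- X[y == "A", d_true] + 4
    acc <- vapply(1:4, function(j) {
      f <- fit_linear_svm(X[, j, drop = FALSE], y, positive = "A")
      mean((predict_decision(f, X[, j, drop = FALSE]) > 0) == (y == "A"))
    }, numeric(1))
    expect_equal(which.max(acc), d_true)
    expect_equal(cvsvm_rank(X, y)$order[1], d_true)
  }
})

test_that("CV-SVM suppresses one of two duplicated informative columns", {
  set.seed(10)
  n <- 30
  f <- c(rnorm(n / 2, 2), rnorm(n / 2, -2))
  X <- cbind(f, f + rnorm(n, 0, 1e-6), rnorm(n))
  y <- factor(rep(c("A", "B"), each = n / 2))
  r <- cvsvm_rank(X, y)
  w <- abs(r$weights[1:2])
  expect_lt(min(w), 1e-6)
  expect_gt(max(w), 0.1)
})

test_that("CV-SVM with no signal returns the zero plane and univariate order", {
  set.seed(11)
  fx <- make_two_group(10, 10, 4, seed = 12)
  r <- cvsvm_rank(fx$X, fx$y)
  expect_true(all(abs(r$weights) < 1e-8))
  expect_equal(r$order, univariate_rank(fx$X, fx$y)$order)
})

test_that("candidate sets are nested prefixes capped at k_final", {
  expect_equal(incremental_candidates(c(3L, 1L, 2L), 5),
               list(3L, c(3L, 1L), c(3L, 1L, 2L)))
  expect_equal(incremental_candidates(c(4L, 2L), 1), list(4L))
  fx <- make_two_group(10, 10, 20, seed = 13)
  ord <- double_ranked <- univariate_rank(fx$X, fx$y, k_initial = 10)$order
  cand <- incremental_candidates(mrmr_rank(fx$X[, ord], fx$y), 5)
  expect_length(cand, 5L)
  for (k in 2:5) expect_equal(cand[[k]][1:(k - 1)], cand[[k - 1]])
})

test_that("ranking depends only on training rows", {
  fx <- make_two_group(10, 10, 15, d = 1, planted = 1:3, seed = 14)
  r1 <- univariate_rank(fx$X, fx$y)
  m1 <- mrmr_rank(fx$X[, r1$order[1:5]], fx$y)
  # a 'test set' appended elsewhere can never influence these objects:
  # recompute from a copy with unrelated extra rows excluded
  X2 <- rbind(fx$X, matrix(1e6, 4, 15))
  r2 <- univariate_rank(X2[1:20, ], fx$y)
  expect_identical(r1$order, r2$order)
  expect_identical(m1$order,
                   mrmr_rank(X2[1:20, r2$order[1:5]], fx$y)$order)
})
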
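# Linear SVM, metric suite and the nested leave-one-out machinery.

test_that("linear SVM matches the libsvm reference implementation", {
  skip_if_not_installed("e1071")
  set.seed(1)
  for (rep in 1:10) {
    n <- 20; d <- 3
    X <- matrix(rnorm(n * d), n, d)
    y <- factor(rep(c("P", "N"), each = n / 2))
    X[y == "P", 1] <- X[y == "P", 1] + 1.5
    fit <- fit_linear_svm(X, y, positive = "P")
    m <- e1071::svm(X, y, kernel = "linear", cost = 1, scale = FALSE)
    w <- as.numeric(t(m$coefs) %*% m$SV)
    dv <- attr(predict(m, X, decision.values = TRUE), "decision.values")
    sgn <- if (colnames(dv)[1] == "P/N") 1 else -1
    expect_equal(unname(fit$beta), sgn * w, tolerance = 5e-3)
    expect_equal(fit$bias, sgn * -m$rho, tolerance = 5e-3)
  }
})

test_that("separable data is classified perfectly and fits are deterministic", {
  X <- matrix(c(-3, -2, -2.5, 2, 2.5, 3), ncol = 1)
  y <- factor(rep(c("neg", "pos"), each = 3))
  f1 <- fit_linear_svm(X, y, positive = "pos")
  expect_true(all(predict(f1, X) == y))
  f2 <- fit_linear_svm(X, y, positive = "pos")
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$bias, f2$bias)
  expect_error(fit_linear_svm(X, factor(rep("pos", 6))), "single class")
})

test_that("a linear kernel cannot solve XOR beyond 3 of 4 corners", {
  X <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0),
             c(0.05, 0.05), c(0.95, 0.95), c(0.05, 0.95), c(0.95, 0.05))
  y <- factor(rep(c("A", "A", "B", "B"), 2))
  fit <- fit_linear_svm(X, y, positive = "A")
  acc <- mean(predict(fit, X) == y)
  expect_lte(acc, 0.75)
})

test_that("metric suite handles the canonical cases", {
  r <- compute_metrics(factor(c("P", "P", "N", "P"), c("P", "N")),
                       c(0.9, 0.8, 0.4, 0.2),
                       factor(c("P", "P", "N", "P"), c("P", "N")), "P")
  expect_equal(r$auc, 2 / 3)
  expect_equal(r$accuracy, 1)
  # perfect separation
  y <- factor(rep(c("P", "N"), each = 4), c("P", "N"))
  rp <- compute_metrics(y, c(4, 3, 2, 1.5, -1, -2, -3, -4), y, "P")
  expect_equal(rp$auc, 1)
  expect_equal(rp$f1, 1)
  # degenerate all-negative classifier
  rd <- compute_metrics(factor(rep("N", 8), c("P", "N")),
                        rep(-1, 8), y, "P")
  expect_equal(rd$sensitivity, 0)
  expect_equal(rd$specificity, 1)
  expect_equal(rd$precision, 0)
  expect_error(compute_metrics(y, 1:8, factor(rep("P", 8), c("P", "N")), "P"),
               "one class absent")
})

test_that("LOO combinatorics: n outer folds, k_optimal within bounds", {
  fx <- make_two_group(5, 5, 8, d = 1.5, planted = 1:2, seed = 2)
  cv <- run_nested_loocv(fx$X, fx$y, k_initial = 5, k_final = 3,
                         positive = "B")
  expect_length(cv$folds, 10L)
  ko <- vapply(cv$folds, `[[`, numeric(1), "k_optimal")
  expect_true(all(ko >= 1 & ko <= 3))
  expect_length(cv$predictions, 10L)
  expect_false(anyNA(cv$decision))
  # every fold's inner loop pools n - 1 = 9 decision values per k
  expect_length(cv$folds[[1]]$inner_auc, 3L)
})

test_that("held-out subjects never influence other folds (leakage guard)", {
  fx <- make_two_group(6, 6, 10, d = 1.2, planted = 1:2, seed = 3)
  cv1 <- run_nested_loocv(fx$X, fx$y, k_initial = 5, k_final = 3,
                          positive = "B")
  X2 <- fx$X
  X2[4, ] <- 1e3 # corrupt one subject's features
  cv2 <- run_nested_loocv(X2, fx$y, k_initial = 5, k_final = 3,
                          positive = "B")
  # fold 4's model was trained without subject 4: identical model
  expect_identical(cv1$folds[[4]]$selected, cv2$folds[[4]]$selected)
  expect_equal(cv1$folds[[4]]$beta, cv2$folds[[4]]$beta)
  # only subject 4's prediction may change
  expect_false(isTRUE(all.equal(cv1$decision[4], cv2$decision[4])))
})

test_that("nested LOOCV recovers a strong planted signal", {
  fx <- make_two_group(10, 10, 20, d = 2.5, planted = 1:3, seed = 4)
  cv <- run_nested_loocv(fx$X, fx$y, k_initial = 10, k_final = 5,
                         positive = "B")
  expect_gt(cv$report$auc, 0.85)
  # selection favours planted elements and k_optimal stays parsimonious
  ko <- vapply(cv$folds, `[[`, numeric(1), "k_optimal")
  expect_lt(mean(ko), 5)
})

test_that("input contracts are enforced", {
  fx <- make_two_group(2, 3, 4, seed = 5)
  expect_error(run_nested_loocv(fx$X, fx$y), "at least 6")
  fx2 <- make_two_group(2, 6, 4, seed = 6)
  expect_error(run_nested_loocv(fx2$X, fx2$y), "at least 3")
})
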
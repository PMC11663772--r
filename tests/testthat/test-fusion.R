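# Concatenation, forced fusion and majority-vote ensembles.

test_that("concatenation sums element counts and prefixes labels", {
  fx <- make_two_group(4, 4, 3, seed = 1)
  sets <- list(a = fx$X, b = fx$X[, 1:2], c = fx$X)
  cc <- concatenate_sets(sets)
  expect_equal(ncol(cc), 8L)
  expect_equal(colnames(cc)[1], "a.e001")
  expect_equal(ncol(concatenate_sets(sets["a"])), 3L)
})

test_that("subject order mismatch errors rather than silently reordering", {
  fx <- make_two_group(4, 4, 3, seed = 2)
  a <- fx$X; rownames(a) <- sprintf("S%d", 1:8)
  b <- a[8:1, ]
  expect_error(concatenate_sets(list(a = a, b = b)), "order mismatch")
  expect_error(concatenate_sets(list(a = a, b = a[1:5, ])), "mismatch")
})

test_that("forced fusion pools the per-set univariate top elements", {
  set.seed(3)
  fx <- make_two_group(8, 8, 30, seed = 3)
  set_index <- rep(c("s1", "s2", "s3"), each = 10)
  sel <- forced_fusion_selector(set_index, per_set = 5)
  cols <- sel(fx$X, fx$y)
  expect_length(cols, 15L)
  expect_equal(as.integer(table(set_index[cols])), rep(5L, 3))
  # sets smaller than per_set contribute everything
  sel2 <- forced_fusion_selector(rep(c("s1", "s2"), c(3, 27)), per_set = 5)
  cols2 <- sel2(fx$X, fx$y)
  expect_equal(sum(cols2 <= 3), 3L)
})

test_that("forced fusion keeps informative-set elements in the model", {
  # one of three sets carries all the signal
  fx <- make_two_group(8, 8, 30, d = 2.5, planted = 1:4, seed = 4)
  sets <- list(sig = fx$X[, 1:10], n1 = fx$X[, 11:20], n2 = fx$X[, 21:30])
  cv <- run_forced_fusion(sets, fx$y, per_set = 3, k_final = 3,
                          positive = "B")
  top_sets <- vapply(cv$folds, function(f)
    any(grepl("^sig\\.", f$elements)), logical(1))
  expect_gte(mean(top_sets), 0.8)
})

test_that("majority voting follows the votes and breaks even ties by score", {
  pred <- list(m1 = c("MDD", "MDD"), m2 = c("MDD", "HC"), m3 = c("HC", "HC"))
  fused <- majority_vote(pred, names(pred), "MDD", "HC")
  expect_equal(as.character(fused), c("MDD", "HC"))
  # unanimity
  expect_equal(as.character(
    majority_vote(pred, c("m1", "m1", "m1"), "MDD", "HC")[1]), "MDD")
  # even count with a tie: decision-value sum decides
  dec <- list(m1 = c(2, -0.5), m2 = c(-0.3, -1))
  expect_message(
    fused2 <- majority_vote(pred[1:2], c("m1", "m2"), "MDD", "HC", dec),
    "tie")
  expect_equal(as.character(fused2), c("MDD", "HC"))
})

test_that("ensemble enumeration matches the binomial coefficients", {
  nm <- sprintf("s%02d", 1:11)
  expect_length(enumerate_ensembles(nm, 3), choose(11, 3)) # 165
  expect_length(enumerate_ensembles(nm, 5), choose(11, 5)) # 462
  expect_length(enumerate_ensembles(nm, 11), 1L)
  expect_error(enumerate_ensembles(nm, 4), "odd")
})

test_that("label-fused ensemble AUC equals balanced accuracy", {
  fx <- make_two_group(8, 8, 10, d = 1.5, planted = 1:2, seed = 5)
  cvs <- lapply(1:3, function(s) {
    fxs <- make_two_group(8, 8, 10, d = 1.5, planted = 1:2, seed = 10 + s)
    run_nested_loocv(fxs$X, fx$y, k_initial = 5, k_final = 3, positive = "B")
  })
  names(cvs) <- c("a", "b", "c")
  er <- ensemble_performance(cvs, c("a", "b", "c"))
  expect_equal(er$report$auc,
               (er$report$sensitivity + er$report$specificity) / 2)
})

test_that("majority vote over independent members beats a single member", {
  # Condorcet-style check on constructed predictions with accuracy p = 0.7
  set.seed(6)
  y <- factor(rep(c("P", "N"), each = 25), c("P", "N"))
  gains <- vapply(1:20, function(r) {
    preds <- lapply(1:5, function(m) {
      flip <- runif(50) > 0.7
      ifelse(flip, ifelse(y == "P", "N", "P"), as.character(y))
    })
    names(preds) <- sprintf("m%d", 1:5)
    fused <- majority_vote(preds, names(preds), "P", "N")
    mean(fused == y) - mean(vapply(preds, function(p) mean(p == y),
                                   numeric(1)))
  }, numeric(1))
  expect_gt(mean(gains), 0)
})
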
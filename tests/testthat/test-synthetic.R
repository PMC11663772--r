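test_that("fixed seed gives bit-identical tables; validation catches misuse", {
  spec <- synthetic_spec(8, 8, set_dims = c(a = 10L, b = 5L),
                         rho = 0.3, seed = 77)
  t1 <- generate_feature_tables(spec)
  t2 <- generate_feature_tables(spec)
  expect_identical(t1, t2)
  expect_equal(dim(t1$a), c(16L, 10L))
  expect_equal(dim(t1$b), c(16L, 5L))
  expect_error(
    synthetic_spec(8, 8, set_dims = c(a = 4L),
                   informative = list(a = list(list(index = 9, d = 1,
                                                    sign = 1)))),
    "outside")
  expect_error(synthetic_spec(8, 8, set_dims = c(a = 4L), rho = 1),
               "rho")
})

test_that("null spec produces null-distributed element t statistics", {
  spec <- synthetic_spec(30, 30, set_dims = c(s = 300L), seed = 5)
  X <- generate_feature_tables(spec)$s
  g <- rep(c(TRUE, FALSE), each = 30)
  tt <- col_ttest(X, g)
  ks <- ks.test(tt$statistic, pt, df = 58)
  expect_gt(ks$p.value, 0.01)
})

test_that("planted effect recovers the requested standardized difference", {
  spec <- synthetic_spec(50, 50, set_dims = c(s = 5L),
                         informative = list(s = list(list(index = 1, d = 2,
                                                          sign = 1))),
                         seed = 21)
  X <- generate_feature_tables(spec)$s
  a <- X[1:50, 1]; b <- X[51:100, 1]
  pooled <- sqrt((var(a) * 49 + var(b) * 49) / 98)
  d_hat <- (mean(b) - mean(a)) / pooled
  expect_gt(d_hat, 1.4)
  expect_lt(d_hat, 2.6)
})

test_that("within-set equicorrelation matches rho", {
  spec <- synthetic_spec(150, 150, set_dims = c(s = 30L), rho = 0.5,
                         seed = 9)
  X <- generate_feature_tables(spec)$s
  C <- cor(X)
  expect_equal(mean(C[upper.tri(C)]), 0.5, tolerance = 0.05)
})

test_that("coupled time series are reproducible and validate the band", {
  spec <- synthetic_spec(2, 2, ts_spec = list(
    n_networks = 4L, n_samples = 200L, dt = 2,
    couplings = list(list(pair = c(1L, 2L), freq = 0.05, phase_lag = 0,
                          strength = 2))), seed = 3)
  s1 <- generate_rsn_timeseries(spec)
  s2 <- generate_rsn_timeseries(spec)
  expect_identical(s1, s2)
  expect_equal(dim(s1[[1]]), c(4L, 200L))
  expect_error(
    synthetic_spec(2, 2, ts_spec = list(
      n_networks = 4L, n_samples = 200L, dt = 2,
      couplings = list(list(pair = c(1L, 2L), freq = 0.3, phase_lag = 0,
                            strength = 2)))),
    "Nyquist")
})

test_that("HDRS generation recovers outcomes exactly at noise rate 0", {
  spec <- synthetic_spec(1, 40, seed = 13)
  assign <- rep(c("PO", "NO"), c(15, 25))
  hd <- generate_hdrs(spec, assign)
  expect_identical(hd$effective, assign)
  lab <- label_outcome(hd$hdrs_baseline, hd$hdrs_followup)
  expect_identical(as.character(lab), assign)
  expect_true(all(hd$hdrs_followup >= 0 & hd$hdrs_followup <= 52))
  expect_true(all(hd$hdrs_baseline >= 1 & hd$hdrs_baseline <= 52))
})

test_that("baseline severity matches the configured distribution", {
  spec <- synthetic_spec(1, 200, seed = 31)
  hd <- generate_hdrs(spec, rep(c("PO", "NO"), 100))
  se <- 4.62 / sqrt(200)
  expect_lt(abs(mean(hd$hdrs_baseline) - 24.4), 3 * se + 0.5) # + rounding
})

test_that("label noise flips assignments at about the configured rate", {
  spec <- synthetic_spec(1, 400, hdrs_model = list(
    baseline_mean = 24.4, baseline_sd = 4.62, po_mean = 0.675, po_sd = 0.08,
    no_mean = 0.30, no_sd = 0.12, noise_rate = 0.2), seed = 17)
  assign <- rep(c("PO", "NO"), 200)
  hd <- generate_hdrs(spec, assign)
  flip_rate <- mean(hd$effective != assign)
  expect_gt(flip_rate, 0.12)
  expect_lt(flip_rate, 0.28)
  lab <- label_outcome(hd$hdrs_baseline, hd$hdrs_followup)
  expect_identical(as.character(lab), hd$effective)
})

test_that("clinical table marks controls without follow-up", {
  spec <- synthetic_spec(5, 6, seed = 2)
  cl <- make_clinical_table(spec)
  expect_equal(nrow(cl), 11L)
  expect_true(all(is.na(cl$hdrs_followup[cl$group == "A"])))
  expect_true(all(!is.na(cl$hdrs_followup[cl$group == "B"])))
  expect_identical(cl$subject_id, sprintf("S%03d", 1:11))
})
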
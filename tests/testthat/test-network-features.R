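# Static FC, edge-matrix vectorization, wavelet coherence and the nCC /
# leadCoh constructors.

test_that("static FC yields 105 Fisher-z elements for 15 networks", {
  set.seed(1)
  ts <- matrix(rnorm(15 * 100), 15, 100)
  v <- static_fc(ts)
  expect_length(v, 105L)
  expect_equal(names(v)[1], "N01~N02")
  expect_equal(names(v)[105], "N14~N15")
})

test_that("static FC caps perfect correlation and rejects constants", {
  set.seed(2)
  x <- rnorm(50)
  ts <- rbind(x, x, rnorm(50))
  v <- static_fc(ts, cap = 1 - 1e-6)
  expect_equal(v[["N01~N02"]], atanh(1 - 1e-6))
  expect_error(static_fc(rbind(x, rep(1, 50))), "constant")
})

test_that("independent noise rarely shows strong static correlation", {
  set.seed(3)
  frac_small <- replicate(10, {
    ts <- matrix(rnorm(15 * 200), 15, 200)
    r <- tanh(static_fc(ts))
    mean(abs(r) < 0.3)
  })
  expect_gte(mean(frac_small), 0.95)
})

test_that("edge vectorization is row-major and invertible", {
  m <- matrix(0, 3, 3)
  m[upper.tri(m)] <- 0 # fill explicitly below
  m[1, 2] <- m[2, 1] <- 12
  m[1, 3] <- m[3, 1] <- 13
  m[2, 3] <- m[3, 2] <- 23
  expect_equal(unname(vectorize_edge_matrix(m)), c(12, 13, 23))
  set.seed(4)
  M <- matrix(rnorm(84 * 84), 84, 84)
  M <- (M + t(M)) / 2
  v <- vectorize_edge_matrix(M)
  expect_length(v, 3486L)
  expect_equal(unvectorize_edge_matrix(v, 84) + diag(diag(M)),
               M, tolerance = 1e-12)
  expect_length(vectorize_edge_matrix(matrix(c(0, 5, 5, 0), 2, 2)), 1L)
  M[1, 2] <- M[1, 2] + 1
  expect_error(vectorize_edge_matrix(M), "symmetric")
})

test_that("identical series give coherence 1, phase 0, one cluster", {
  set.seed(5)
  x <- as.vector(arima.sim(list(ar = 0.5), 300))
  m <- wavelet_coherence(x, x, dt = 2)
  expect_gt(min(m$coh[m$in_coi]), 0.999)
  expect_lt(max(abs(m$phase[m$in_coi])), 1e-6)
  expect_equal(count_coherence_clusters(m), 1L)
})

test_that("quarter-period lag shows phase pi/2 with the leader identified", {
  set.seed(6)
  dt <- 2; tt <- (0:299) * dt
  x <- cos(2 * pi * 0.05 * tt) + 0.3 * rnorm(300)
  y <- cos(2 * pi * 0.05 * (tt - 5)) + 0.3 * rnorm(300) # x leads by 5 s
  m <- wavelet_coherence(x, y, dt)
  sc <- which.min(abs(m$periods - 20))
  ph <- m$phase[sc, m$in_coi[sc, ]]
  expect_equal(mean(ph), pi / 2, tolerance = 0.1)
  expect_gt(lead_coherence(m), 0.5)
  # swapped pair: magnitude preserved, phase negated
  ms <- wavelet_coherence(y, x, dt)
  expect_equal(ms$coh, m$coh, tolerance = 1e-10)
  expect_equal(ms$phase, -m$phase, tolerance = 1e-10)
})

test_that("coherence magnitude is invariant under amplitude rescaling", {
  set.seed(7)
  x <- rnorm(200); y <- rnorm(200)
  m1 <- wavelet_coherence(x, y, dt = 2)
  m2 <- wavelet_coherence(5 * x, 0.1 * y, dt = 2)
  expect_equal(m1$coh, m2$coh, tolerance = 1e-10)
})

test_that("nCC is invariant under joint time reversal", {
  set.seed(8)
  dt <- 2; tt <- (0:255) * dt
  x <- sin(2 * pi * 0.04 * tt) + rnorm(256)
  y <- sin(2 * pi * 0.04 * tt + 0.4) + rnorm(256)
  m <- wavelet_coherence(x, y, dt)
  mr <- wavelet_coherence(rev(x), rev(y), dt)
  expect_equal(count_coherence_clusters(m), count_coherence_clusters(mr))
})

test_that("series shorter than the largest scale support are rejected", {
  expect_error(wavelet_coherence(rnorm(64), rnorm(64), dt = 2), "support")
  expect_error(wavelet_coherence(rnorm(10), rnorm(12), dt = 2), "equal length")
})

test_that("cluster counting matches a flood-fill oracle and handles blobs", {
  empty <- make_map(matrix(0, 6, 8), matrix(0, 6, 8))
  expect_equal(count_coherence_clusters(empty), 0L)
  one <- make_map(matrix(0, 6, 8), matrix(0, 6, 8))
  one$mask[2:4, 2:5] <- TRUE
  expect_equal(count_coherence_clusters(one), 1L)
  two <- make_map(matrix(0, 6, 10), matrix(0, 6, 10))
  two$mask[2:3, 2:3] <- TRUE
  two$mask[2:3, 7:9] <- TRUE # separated in time, same phase bin
  expect_equal(count_coherence_clusters(two), 2L)
  # same support, two phase categories -> split into two clusters
  split <- make_map(matrix(0, 6, 8), matrix(0, 6, 8))
  split$mask[2:5, 3:6] <- TRUE
  split$phase[2:3, ] <- 0        # in-phase
  split$phase[4:5, ] <- pi       # out-of-phase
  expect_equal(count_coherence_clusters(split), 2L)
})

test_that("cluster counting agrees with EBImage connected components", {
  skip_if_not_installed("EBImage")
  set.seed(9)
  for (rep in 1:10) {
    nr <- 12; nc <- 20
    mask <- matrix(runif(nr * nc) < 0.35, nr, nc)
    phase <- matrix(runif(nr * nc, -pi, pi), nr, nc)
    m <- make_map(matrix(1, nr, nc), phase, mask = mask)
    cat_m <- mddfusion:::phase_category(phase)
    cat_m[!mask] <- 0L
    cat_m <- matrix(cat_m, nr, nc)
    oracle <- sum(vapply(1:4, function(k) {
      lab <- EBImage::bwlabel(cat_m == k)
      max(lab)
    }, numeric(1)))
    expect_equal(count_coherence_clusters(m), as.integer(oracle))
  }
})

test_that("lead coherence is directional and symmetric at zero phase", {
  zero <- make_map(matrix(1, 4, 6), matrix(0, 4, 6))
  rev_zero <- zero; rev_zero$phase <- -zero$phase
  expect_equal(lead_coherence(zero), lead_coherence(rev_zero))
  lead <- make_map(matrix(1, 4, 6), matrix(pi / 3, 4, 6))
  lag <- lead; lag$phase <- -lead$phase
  expect_equal(lead_coherence(lead), 1)
  expect_equal(lead_coherence(lag), 0)
  expect_gt(lead_coherence(lead), lead_coherence(lag))
  expect_gt(lead_coherence(lead, "weighted"), 0.5)
})

test_that("network feature sets have the canonical element counts", {
  set.seed(10)
  spec <- synthetic_spec(1, 1, ts_spec = list(
    n_networks = 5L, n_samples = 220L, dt = 2,
    couplings = list(list(pair = c(1L, 2L), freq = 0.05, phase_lag = pi / 2,
                          strength = 2))), seed = 11)
  series <- generate_rsn_timeseries(spec)
  fs <- network_feature_sets(series, dt = 2)
  expect_equal(ncol(fs$sFC), choose(5, 2))
  expect_equal(ncol(fs$nCC), choose(5, 2))
  expect_equal(ncol(fs$leadCoh), 5L * 4L)
  expect_equal(colnames(fs$leadCoh)[1], "N01->N02")
  # coupled pair with positive lag: N01 leads N02
  expect_gt(fs$leadCoh[1, "N01->N02"], fs$leadCoh[1, "N02->N01"])
})
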
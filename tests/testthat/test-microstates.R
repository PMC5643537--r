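test_that("GFP is the spatial SD and is homogeneous of degree 1", {
  expect_equal(gfp(matrix(0, 4, 3)), c(0, 0, 0))
  expect_equal(gfp(matrix(c(1, -1), 2, 1)), 1)   # population SD of (1,-1)
  X <- matrix(rnorm(8 * 20), 8)
  expect_equal(gfp(3.5 * X), 3.5 * gfp(X), tolerance = 1e-12)
  expect_error(gfp(matrix(1, 1, 5)), "2 channels")
})

test_that("GFP peak finding returns strict local maxima", {
  expect_length(find_gfp_peaks(1:10), 0L)
  expect_equal(find_gfp_peaks(c(0, 1, 0, 2, 0)), c(2L, 4L))
  truth <- tiny_truth(seed = 2)
  sim <- simulate_eeg(truth, 20, 128, snr = 1e5, seed = 1, states = 1:4)
  pk <- find_gfp_peaks(gfp(sim$rec$data))
  n_dwell <- length(rle(sim$labels)$lengths)
  expect_gte(length(pk), n_dwell)   # >= one envelope peak per dwell period
})

test_that("polarity-invariant k-means recovers separable clusters", {
  set.seed(3)
  base <- normalize_maps(matrix(rnorm(3 * 16), 3))
  base <- normalize_maps(t(qr.Q(qr(t(base)))[, 1:3]))   # orthogonal maps
  X <- base[rep(1:3, each = 10), ]
  fit <- modified_kmeans(X, 3, n_init = 5, seed = 1)
  expect_equal(fit$ev, 1, tolerance = 1e-9)
  m <- match_sets(fit$msset, microstate_set(base))
  expect_true(all(m$mapping$corr > 1 - 1e-9))

  # a map and its sign-flip belong to one state
  pair <- rbind(base[1, ], -base[1, ], base[2, ], -base[2, ])
  fit2 <- modified_kmeans(pair, 2, n_init = 5, seed = 2)
  expect_equal(fit2$assignment[1], fit2$assignment[2])
  expect_equal(fit2$assignment[3], fit2$assignment[4])
  expect_error(modified_kmeans(X, 30, n_init = 2, seed = 1))
})

test_that("k-means attains the exhaustive-partition optimum on small inputs", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- normalize_maps(matrix(rnorm(6 * 10), 6))
    fit <- modified_kmeans(X, 2, n_init = 50, seed = seed)
    oracle <- best_partition_objective(X, 2L)
    expect_equal(fit$ev * nrow(X), oracle, tolerance = 1e-8)
  }
})

test_that("the CV criterion matches its closed form and vanishes at perfect fit", {
  # perfect fit: every map proportional to its template
  t1 <- c(2, -1, -1) / sqrt(6)
  X <- rbind(3 * t1, -0.5 * t1)
  ms <- microstate_set(matrix(t1, 1))
  expect_equal(cv_criterion(X, ms), 0, tolerance = 1e-12)

  # hand-evaluated 2x3 instance: C=3, K=1, factor ((C-1)/(C-1-K))^2 = 4
  X2 <- rbind(c(1, 0, -1), c(0.5, 0.5, -1))
  X2c <- X2 - rowMeans(X2)
  proj <- as.vector(X2c %*% t1)
  sigma2 <- mean((rowSums(X2c^2) - proj^2) / 2)
  expect_equal(cv_criterion(X2, ms), sigma2 * 4, tolerance = 1e-12)
  expect_error(cv_criterion(X2, microstate_set(rbind(t1, c(1, -1, 0)))),
               "undefined")
})

test_that("CV model-order selection recovers the planted state count", {
  hits <- 0L
  for (seed in 1:10) {
    truth <- ground_truth(n_states = 4, seed = 100 + seed)
    sim <- simulate_eeg(truth, 60, 128, snr = 5, seed = 200 + seed)
    pk <- find_gfp_peaks(gfp(sim$rec$data))
    ms <- select_k(t(sim$rec$data[, pk]), 2:7, n_init = 4, seed = seed)
    if (nrow(ms$maps) == 4L) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("select_k breaks ties toward smaller K and handles 1-state data", {
  # degenerate single-topography data: residual noise is flat in K, so the
  # increasing penalty makes the smallest K the minimum
  truth <- ground_truth(n_states = 1, n_rest_states = 1, n_channels = 16,
                        seed = 5)
  sim <- simulate_eeg(truth, 10, 128, snr = 20, seed = 6)
  pk <- find_gfp_peaks(gfp(sim$rec$data))
  ms <- select_k(t(sim$rec$data[, pk]), 2:5, n_init = 3, seed = 7)
  curve <- attr(ms, "cv_curve")
  expect_equal(nrow(ms$maps), curve$K[which.min(curve$cv)])
  expect_error(select_k(matrix(rnorm(50), 10), integer(0)), "empty")
})

test_that("explained variance is non-decreasing in K", {
  truth <- tiny_truth(seed = 8)
  sim <- simulate_eeg(truth, 15, 128, snr = 3, seed = 9)
  pk <- find_gfp_peaks(gfp(sim$rec$data))
  X <- t(sim$rec$data[, pk])
  evs <- vapply(2:6, function(K)
    modified_kmeans(X, K, n_init = 8, seed = K)$ev, 0)
  expect_true(all(diff(evs) > -1e-6))
})

test_that("negating the input leaves clustering quantities unchanged", {
  truth <- tiny_truth(seed = 10)
  sim <- simulate_eeg(truth, 10, 128, snr = 5, seed = 11)
  pk <- find_gfp_peaks(gfp(sim$rec$data))
  X <- t(sim$rec$data[, pk])
  a <- modified_kmeans(X, 4, n_init = 5, seed = 3)
  b <- modified_kmeans(-X, 4, n_init = 5, seed = 3)
  expect_equal(a$ev, b$ev, tolerance = 1e-10)
  expect_identical(a$assignment, b$assignment)
  expect_equal(cv_criterion(X, a$msset, a$assignment),
               cv_criterion(-X, b$msset, b$assignment), tolerance = 1e-10)
})

test_that("back-fitting labels by absolute spatial correlation", {
  truth <- tiny_truth(seed = 12)
  ms <- truth_msset(truth)
  m <- truth$topographies[[2]]
  rec <- recording(outer(m, c(5, 2, -3, 0.1)), 128)
  seg <- backfit(rec, ms)
  expect_equal(seg$labels[c(1, 2, 3)], c(2L, 2L, 2L))
  expect_equal(seg$labels[3], 2L)       # negated map: same state
  # zero-variance sample carries the previous label
  rec2 <- recording(cbind(outer(m, c(1, 1)), 0, outer(m, 1)), 128)
  expect_equal(backfit(rec2, ms)$labels[3], 2L)
})

test_that("temporal smoothing enforces the minimum segment duration", {
  # worked example at 128 Hz: 23 ms -> 3 samples
  lab <- c(rep(1L, 10), 2L, rep(1L, 10))
  seg <- segmentation(lab, rep(1, 21), 128)
  sm <- smooth_segmentation(seg)
  expect_equal(sm$labels, rep(1L, 21))

  smooth_in <- segmentation(rep(c(1L, 2L), each = 20), rep(1, 40), 128)
  expect_equal(smooth_segmentation(smooth_in)$labels, smooth_in$labels)

  set.seed(13)
  for (i in 1:100) {
    n <- sample(50:300, 1)
    k <- sample(2:5, 1)
    seg <- segmentation(sample.int(k, n, TRUE), runif(n), 128,
                        corr = matrix(runif(n * k), n, k))
    sm <- smooth_segmentation(seg)
    expect_gte(min(sm$segments$end - sm$segments$start), 3L)
  }
  expect_error(smooth_segmentation(segmentation(1L, 1, 128)), "shorter")
})

test_that("set matching equals the exhaustive-permutation optimum", {
  truth <- tiny_truth(seed = 14)
  ms <- truth_msset(truth)
  self <- match_sets(ms, ms)
  expect_equal(self$mapping$ref, self$mapping$map)
  expect_true(all(self$mapping$corr > 1 - 1e-9))
  flipped <- microstate_set(-ms$maps)
  expect_true(all(match_sets(ms, flipped)$mapping$corr > 1 - 1e-9))

  for (seed in 1:5) {
    set.seed(seed)
    A <- microstate_set(matrix(rnorm(3 * 12), 3))
    B <- microstate_set(matrix(rnorm(3 * 12), 3))
    got <- match_sets(A, B)
    C <- abs(A$maps %*% t(B$maps))
    perms <- rbind(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
    oracle <- max(apply(perms, 1, function(p) sum(C[cbind(1:3, p)])))
    expect_equal(sum(got$mapping$corr), oracle, tolerance = 1e-12)
  }
})

test_that("group clustering groups identical subjects perfectly", {
  truth <- tiny_truth(seed = 15)
  ms <- truth_msset(truth)
  sets <- list(ms, ms, ms)
  g <- group_cluster(sets, K = 5, seed = 1)
  expect_equal(g$consistency, 1, tolerance = 1e-9)
  m <- match_sets(g$templates, ms)
  expect_true(all(m$mapping$corr > 1 - 1e-9))
  single <- group_cluster(list(ms), K = 5, seed = 1)
  expect_equal(sort(single$mapping[[1]]), 1:5)
  expect_error(group_cluster(sets, K = 3), "smaller")
})

test_that("temporal statistics summarize durations, coverage, occurrence", {
  seg <- segmentation(rep(1L, 128), rep(1, 128), 128)
  ts <- temporal_stats(seg)
  expect_equal(ts$coverage, 1)
  expect_equal(ts$occurrences_per_s, 1)

  seg2 <- segmentation(rep(rep(c(1L, 2L), each = 10), 10), rep(1, 200), 128)
  ts2 <- temporal_stats(seg2)
  expect_equal(ts2$mean_duration_ms, c(78.125, 78.125))
  expect_equal(sum(ts2$coverage), 1)
})
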
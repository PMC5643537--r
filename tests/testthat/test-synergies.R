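test_that("NNMF recovers realizable factorizations", {
  set.seed(1)
  W0 <- matrix(runif(10 * 3), 10, 3)
  H0 <- matrix(runif(3 * 80), 3, 80)
  V <- W0 %*% H0
  m <- nnmf(V, 3, n_restarts = 10, seed = 2)
  expect_gte(m$vaf, 0.999)

  v1 <- runif(10); h1 <- runif(60)
  r1 <- nnmf(v1 %o% h1, 1, n_restarts = 3, seed = 3)
  expect_gt(stats::cor(r1$W[, 1], v1), 0.999)
  expect_error(nnmf(-V, 2), "nonnegative")
  expect_error(nnmf(V, 0), "K must be")
})

test_that("the multiplicative-update objective never increases", {
  set.seed(4)
  for (i in 1:5) {
    V <- matrix(runif(12 * 50), 12, 50)
    tr <- attr(nnmf(V, sample(2:4, 1), n_restarts = 1, max_iter = 200,
                    seed = i), "obj_trace")
    expect_true(all(diff(tr) <= 1e-8 * tr[1]))
  }
})

test_that("VAF matches hand computation and its boundary values", {
  V <- matrix(c(1, 2, 3, 4), 2, 2)
  model <- list(W = matrix(c(1, 0), 2, 1), H = matrix(c(1, 3), 1, 2))
  # residual = V - WH = [[0, 0], [2, 4]]; 1 - 20/30
  expect_equal(vaf(V, model), 1 - 20 / 30)
  expect_equal(vaf(V, list(W = V, H = diag(2))), 1)
  expect_equal(vaf(V, list(W = matrix(0, 2, 1), H = matrix(0, 1, 2))), 0)
})

test_that("VAF-threshold order selection and its boundaries behave", {
  truth <- tiny_truth(seed = 5)
  tr <- simulate_trial_emg(truth, "cylindrical", noise_sd = 0, seed = 1)
  m <- select_n_synergies(tr$rec$data, k_max = 7, n_restarts = 4, seed = 2)
  expect_equal(ncol(m$W), 5L)
  expect_gt(m$vaf, 0.98)

  # threshold 0: a single synergy suffices
  m1 <- select_n_synergies(tr$rec$data, k_max = 7, threshold = 0,
                           n_restarts = 2, seed = 3)
  expect_equal(ncol(m1$W), 1L)

  # i.i.d. noise is unreachable at small k_max: flagged
  set.seed(6)
  noise <- matrix(runif(10 * 200), 10, 200)
  expect_warning(mf <- select_n_synergies(noise, k_max = 2, n_restarts = 2,
                                          seed = 4), "unreachable")
  expect_true(mf$flagged)
})

test_that("VAF is non-decreasing in K and scale invariant", {
  truth <- tiny_truth(seed = 7)
  V <- simulate_trial_emg(truth, "reach", noise_sd = 0.05, seed = 2)$rec$data
  vafs <- vapply(1:6, function(K) nnmf(V, K, n_restarts = 4, seed = K)$vaf, 0)
  expect_true(all(diff(vafs) > -1e-6))
  for (c in c(0.1, 7)) {
    vc <- vapply(1:6, function(K) nnmf(c * V, K, n_restarts = 4, seed = K)$vaf, 0)
    expect_equal(vc, vafs, tolerance = 1e-6)
  }
})

test_that("synergy matching equals the exhaustive-permutation optimum", {
  set.seed(8)
  W <- matrix(runif(10 * 3), 10, 3)
  self <- match_synergies(W, W)
  expect_equal(self$mapping$dot, rep(1, 3), tolerance = 1e-12)

  orth <- diag(4)[, 1:3]
  m <- match_synergies(orth, diag(4)[, c(4, 4, 4)])
  expect_equal(length(m$unmatched), 3L)

  for (seed in 1:5) {
    set.seed(seed)
    A <- matrix(runif(8 * 3), 8, 3); B <- matrix(runif(8 * 3), 8, 3)
    got <- match_synergies(A, B)
    na <- sweep(A, 2, sqrt(colSums(A^2)), "/")
    nb <- sweep(B, 2, sqrt(colSums(B^2)), "/")
    D <- crossprod(na, nb)
    perms <- rbind(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
    oracle <- max(apply(perms, 1, function(p) sum(D[cbind(1:3, p)])))
    expect_equal(sum(got$mapping$dot), oracle, tolerance = 1e-12)
  }
})

test_that("reference synergies recover planted weight groups", {
  truth <- tiny_truth(seed = 9)
  W <- truth$synergy_weights
  refs <- build_reference_set(list(W, W, W), k = 5)
  m <- match_synergies(refs$reference, W)
  expect_true(all(m$mapping$dot > 1 - 1e-9))

  # two well-separated groups across subjects
  g1 <- c(1, 1, 0, 0, 0, 0); g2 <- c(0, 0, 0, 0, 1, 1)
  Ws <- lapply(1:4, function(i) cbind(g1 + runif(6, 0, 0.05),
                                      g2 + runif(6, 0, 0.05)))
  r2 <- build_reference_set(Ws, k = 2)
  expect_equal(sort(as.integer(table(r2$cluster))), c(4L, 4L))
  single <- build_reference_set(list(W), k = 5)
  expect_equal(ncol(single$reference), 5L)
})

test_that("synergy temporal occurrence is the windowed putative-EMG correlation", {
  # single-synergy EMG against its own model: correlation 1 where active
  w <- c(1, 2, 0.5); h <- c(0, 1, 2, 3, 1, 0, 0, 0, 0, 0)
  V <- w %o% h
  model <- synergy_model(matrix(w), matrix(h, 1))
  grid <- data.frame(start = c(0, 0.5), end = c(0.5, 1), phase = "execution")
  occ <- synergy_occurrence(model, list(V), grid, rate = 10)
  expect_equal(occ$values[1, 1], 1, tolerance = 1e-9)
  expect_equal(occ$values[1, 2], 0)   # zero activation window -> 0, logged
  expect_equal(attr(occ, "degenerate")[1, 2], 1L)

  # two-synergy hand case: oracle via direct Pearson correlation
  set.seed(10)
  W2 <- matrix(runif(6 * 2), 6, 2)
  H2 <- matrix(runif(2 * 4), 2, 4)
  V2 <- W2 %*% H2 + matrix(runif(24, 0, 0.1), 6, 4)
  model2 <- synergy_model(W2, H2)
  g2 <- data.frame(start = 0, end = 1, phase = "execution")
  occ2 <- synergy_occurrence(model2, list(V2), g2, rate = 4)
  for (k in 1:2)
    expect_equal(occ2$values[k, 1],
                 stats::cor(as.vector(model2$W[, k] %o% model2$H[k, ]),
                            as.vector(V2)),
                 tolerance = 1e-12)
})
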
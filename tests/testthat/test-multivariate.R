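mk_occ <- function(vals, start, end) {
  occurrence_matrix(vals, data.frame(start = start, end = end,
                                     phase = "execution"))
}

test_that("occurrence stacking aligns windows by their time stamps", {
  set.seed(1)
  A <- mk_occ(matrix(runif(12), 3, 4), start = 0:3 / 10, end = 1:4 / 10)
  B <- mk_occ(matrix(runif(8), 2, 4), start = 0:3 / 10, end = 1:4 / 10)
  st <- stack_occurrences(list(A), list(B))
  expect_equal(nrow(st$X), nrow(st$Y))
  expect_equal(dim(st$X), c(4L, 3L))

  # 4 task blocks -> 4x the rows
  st4 <- stack_occurrences(rep(list(A), 4), rep(list(B), 4))
  expect_equal(nrow(st4$X), 16L)

  # partially overlapping grids keep only the common windows
  Bwide <- mk_occ(matrix(runif(12), 2, 6), start = -2:3 / 10, end = -1:4 / 10)
  sto <- stack_occurrences(list(A), list(Bwide))
  expect_equal(nrow(sto$X), 4L)

  Boff <- mk_occ(matrix(runif(8), 2, 4), start = 0:3 / 10 + 0.05,
                 end = 1:4 / 10 + 0.05)
  expect_error(stack_occurrences(list(A), list(Boff)), "alignable")
})

test_that("canonical correlation hits 1 on copies and stays in the null band on noise", {
  set.seed(2)
  X <- matrix(rnorm(50 * 4), 50, 4)
  cc <- cca(X, X)
  expect_equal(cc$cor, rep(1, 4), tolerance = 1e-9)
  expect_true(all(diff(cc$cor) <= 1e-9))
  expect_equal(colSums(cc$xcoef^2), rep(1, 4), tolerance = 1e-9)

  Y <- matrix(rnorm(50 * 3), 50, 3)
  obs <- cca(X, Y)$cor[1]
  sur <- cca_surrogate(X, Y, n_perm = 100, seed = 3)
  expect_lt(obs, stats::quantile(sur[, 1], 0.99))
  expect_gt(obs, stats::quantile(sur[, 1], 0.005))
})

test_that("canonical correlation matches a unit-vector grid-search oracle", {
  set.seed(4)
  for (i in 1:3) {
    X <- matrix(rnorm(30 * 3), 30, 3)
    Y <- matrix(rnorm(30 * 3), 30, 3)
    got <- cca(X, Y)$cor[1]
    # oracle: maximize |cor(Xa, Yb)| over a dense random grid of unit
    # vectors (independent of the eigen-decomposition route)
    A <- matrix(rnorm(3 * 700), 3, 700)
    A <- sweep(A, 2, sqrt(colSums(A^2)), "/")
    oracle <- max(abs(stats::cor(X %*% A, Y %*% A)))
    expect_lt(abs(got - oracle), 0.02)
    expect_gte(got + 1e-9, oracle)
  }
})

test_that("CCA correlations are invariant to column rescaling", {
  set.seed(5)
  X <- matrix(rnorm(40 * 3), 40, 3)
  Y <- matrix(rnorm(40 * 3), 40, 3)
  base <- cca(X, Y)$cor
  for (s in c(0.01, 1, 250)) {
    Xs <- X; Xs[, 2] <- Xs[, 2] * s
    Ys <- Y; Ys[, 1] <- Ys[, 1] * s
    expect_equal(cca(Xs, Ys)$cor, base, tolerance = 1e-8)
  }
})

test_that("component significance uses the signed-rank surrogate baseline", {
  # 8 subjects all above their surrogates: exact one-sided signed-rank
  cors <- matrix(seq(0.8, 0.94, 0.02), 8, 1)
  set.seed(20)
  sur <- cors - runif(8, 0.2, 0.4)     # distinct differences: exact test
  expect_lt(cca_significance(cors, sur), 0.05)
  expect_equal(cca_significance(cors, sur), 1 / 256, tolerance = 1e-12)
  expect_gte(cca_significance(cors, cors), 0.5)
  expect_error(cca_significance(cors[1, , drop = FALSE], sur[1, , drop = FALSE]),
               "single subject")
})

test_that("preparation features are windows x states one-hots", {
  occs <- random_occupancies(3, 5, 20)
  f <- build_feature_vectors(occs)
  expect_equal(dim(f), c(3L, 100L))
  expect_equal(rowSums(f), rep(20, 3))
  allB <- matrix(0, 5, 20); allB[2, ] <- 1
  fB <- build_feature_vectors(list(allB))
  expect_equal(sum(fB), 20)
  expect_equal(build_feature_vectors(occs[c(1, 1)])[1, ],
               build_feature_vectors(occs[c(1, 1)])[2, ])
})

test_that("the decoder is perfect on separable classes and reproducible", {
  set.seed(6)
  lab <- rep(c("a", "b", "c", "d"), each = 8)
  f <- matrix(0, 32, 8)
  f[cbind(seq_len(32), 2 * match(lab, letters[1:4]))] <- 1
  dec <- lda_decode(f, lab, n_reps = 10, seed = 1)
  expect_equal(unname(diag(dec$confusion)), rep(100, 4))
  dec2 <- lda_decode(f, lab, n_reps = 10, seed = 1)
  expect_identical(dec$confusion, dec2$confusion)
  few <- c(1, 9, 17, 25, 2)            # one class with fewer than 4 epochs
  expect_error(lda_decode(f[few, ], lab[few]), "at least 4")
})

test_that("shrinkage LDA agrees with the classic solver when well-conditioned", {
  skip_if_not_installed("MASS")
  set.seed(7)
  n <- 40
  X <- rbind(matrix(rnorm(n * 3, 0), n, 3), matrix(rnorm(n * 3, 1.5), n, 3))
  y <- rep(c("a", "b"), each = n)
  fit <- microsyn:::shrinkage_lda_fit(X, y, lambda = 1e-6)
  ours <- microsyn:::shrinkage_lda_predict(fit, X)
  ref <- as.character(stats::predict(MASS::lda(X, grouping = y), X)$class)
  expect_gt(mean(ours == ref), 0.99)
})

test_that("the permutation null of the decoder sits at chance", {
  set.seed(8)
  lab <- rep(c("a", "b", "c", "d"), each = 10)
  f <- matrix(runif(40 * 12), 40, 12)   # no class structure
  null <- suppressWarnings(lda_null(f, lab, n_null = 300, seed = 2))
  expect_lt(abs(null$significance_level - 25), 3)
  null2 <- suppressWarnings(lda_null(f, lab, n_null = 50, seed = 2))
  null3 <- suppressWarnings(lda_null(f, lab, n_null = 50, seed = 2))
  expect_identical(null2$null_accuracy, null3$null_accuracy)
  expect_warning(lda_null(f, lab, n_null = 50, seed = 2), "fewer than 100")
})

test_that("decoding accuracy grows with planted occupancy separation", {
  acc_at <- function(sep, seed = 3) {
    set.seed(seed)
    lab <- rep(c("a", "b", "c", "d"), each = 12)
    occs <- lapply(seq_along(lab), function(i) {
      probs <- rep(1, 5)
      probs[match(lab[i], letters[1:4])] <- 1 + sep
      random_occupancies(1, 5, 20, probs = probs)[[1]]
    })
    f <- build_feature_vectors(occs)
    mean(lda_decode(f, lab, n_reps = 20, seed = 4)$accuracy)
  }
  accs <- vapply(c(0, 2, 8), acc_at, 0)
  expect_true(all(diff(accs) > 0))
  expect_lt(abs(accs[1] - 25), 12)
})

test_that("residualization removes nuisance structure and is idempotent", {
  set.seed(9)
  n <- 30
  nuis <- matrix(rnorm(n * 2), n, 2)
  # orthogonal target: centered and orthogonalized against the nuisance
  tgt <- matrix(rnorm(n * 3), n, 3)
  tgt <- residualize_features(tgt, nuis)
  expect_equal(residualize_features(tgt, nuis), tgt, tolerance = 1e-9)

  copy <- residualize_features(nuis, nuis)
  expect_lt(max(abs(copy)), 1e-9)

  # hand univariate 3-sample case: y on x with intercept
  x <- matrix(c(1, 2, 3), 3, 1); y <- matrix(c(2, 2, 5), 3, 1)
  fit <- stats::lm(y ~ x)
  expect_equal(as.vector(residualize_features(y, x)),
               unname(stats::residuals(fit)), tolerance = 1e-12)
})

test_that("coefficient stability flags planted informative features", {
  set.seed(10)
  lab <- rep(c("a", "b", "c", "d"), each = 10)
  f <- matrix(runif(40 * 10), 40, 10)
  f[, 3] <- f[, 3] + 2 * (lab == "b")        # planted informative feature
  dec <- lda_decode(f, lab, n_reps = 100, seed = 5)
  null <- suppressWarnings(lda_null(f, lab, n_null = 100, seed = 6,
                                    return_coefs = TRUE))
  st <- coefficient_stability(dec$coef_mean, dec$coef_sd, null$coef_ratio)
  expect_true(any(st$significant[3, ]))

  # constant coefficients: capped and flagged
  st2 <- coefficient_stability(matrix(1, 2, 2), matrix(0, 2, 2),
                               null_ratios = c(0.1, 0.2))
  expect_true(all(st2$capped))
  expect_equal(st2$ratio, matrix(100, 2, 2))
  # zero-mean noisy coefficient: small ratio, not significant
  st3 <- coefficient_stability(0.001, 1, null_ratios = runif(100, 0.5, 2))
  expect_false(st3$significant)
})
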
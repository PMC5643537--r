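#' Stack paired occurrence matrices over tasks and phases
#'
#' Builds the paired row-aligned matrices consumed by [cca()]: each row is
#' one time window, stacked over the supplied task/phase blocks; the X
#' columns are microstates and the Y columns are synergies.  Within each
#' paired block, windows are aligned on their time stamps and only windows
#' present in both grids (equal boundaries within 1 ms) are used — for the
#' preparation phase this restricts to the interval where both occurrence
#' definitions exist.
#'
#' @param x_blocks,y_blocks lists (same length) of [occurrence_matrix()]
#'   objects; block i of x is paired with block i of y.
#' @return list with matrices `X` (windows x states), `Y` (windows x
#'   synergies) and `block` (block index per row).
#' @export
stack_occurrences <- function(x_blocks, y_blocks) {
  if (length(x_blocks) != length(y_blocks)) stop("block count mismatch")
  X <- NULL; Y <- NULL; block <- integer(0)
  for (i in seq_along(x_blocks)) {
    gx <- x_blocks[[i]]$grid; gy <- y_blocks[[i]]$grid
    keyx <- paste(round(gx$start, 3), round(gx$end, 3))
    keyy <- paste(round(gy$start, 3), round(gy$end, 3))
    common <- intersect(keyx, keyy)
    if (length(common) == 0L)
      stop(sprintf("block %d: no alignable windows between the two grids", i))
    ix <- match(common, keyx); iy <- match(common, keyy)
    X <- rbind(X, t(x_blocks[[i]]$values[, ix, drop = FALSE]))
    Y <- rbind(Y, t(y_blocks[[i]]$values[, iy, drop = FALSE]))
    block <- c(block, rep(i, length(common)))
  }
  list(X = X, Y = Y, block = block)
}

#' Canonical correlation between microstate and synergy occurrences
#'
#' Centers both sides, drops linearly dependent columns (with a warning)
#' and computes the canonical correlations and weight vectors; weight
#' vectors are normalized by their Euclidean norm (the form in which they
#' are averaged across subjects).
#'
#' @param X windows x states matrix.
#' @param Y windows x synergies matrix.
#' @param subject subject id carried in the result.
#' @return object of class `canonical_result`: `cor` (non-increasing, in
#'   [0, 1]), `xcoef`, `ycoef` (unit-norm columns), `xcols`, `ycols`
#'   (columns retained), `p` (filled by [cca_significance()]).
#' @export
cca <- function(X, Y, subject = NA) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  drop_dependent <- function(M, side) {
    Mc <- scale(M, center = TRUE, scale = FALSE)
    q <- qr(Mc)
    keep <- sort(q$pivot[seq_len(q$rank)])
    if (q$rank < ncol(M))
      warning(sprintf("%s: dropped %d linearly dependent column(s)", side,
                      ncol(M) - q$rank))
    list(M = M[, keep, drop = FALSE], keep = keep)
  }
  dx <- drop_dependent(X, "X"); dy <- drop_dependent(Y, "Y")
  if (nrow(X) <= ncol(dx$M) || nrow(Y) <= ncol(dy$M))
    stop("need more rows (windows) than columns on each side")
  cc <- stats::cancor(dx$M, dy$M)
  unitcols <- function(A) sweep(A, 2L, pmax(sqrt(colSums(A^2)), 1e-15), "/")
  structure(list(cor = cc$cor,
                 xcoef = unitcols(cc$xcoef[, seq_along(cc$cor), drop = FALSE]),
                 ycoef = unitcols(cc$ycoef[, seq_along(cc$cor), drop = FALSE]),
                 xcols = dx$keep, ycols = dy$keep,
                 p = rep(NA_real_, length(cc$cor)), subject = subject),
            class = "canonical_result")
}

#' @export
print.canonical_result <- function(x, ...) {
  cat(sprintf("<canonical_result> subject=%s, correlations: %s\n", x$subject,
              paste(sprintf("%.3f", x$cor), collapse = ", ")))
  invisible(x)
}

#' Surrogate canonical correlations by row permutation
#'
#' Null canonical correlations obtained by permuting the rows of Y
#' (breaking the window-wise pairing while preserving both marginals).
#'
#' @inheritParams cca
#' @param n_perm number of surrogates.
#' @param seed integer seed.
#' @return matrix (n_perm x components) of surrogate correlations.
#' @export
cca_surrogate <- function(X, Y, n_perm = 100L, seed = 1L) {
  set.seed(seed)
  ncomp <- length(suppressWarnings(cca(X, Y)$cor))
  out <- matrix(NA_real_, n_perm, ncomp)
  for (i in seq_len(n_perm)) {
    ci <- suppressWarnings(cca(X, Y[sample.int(nrow(Y)), , drop = FALSE])$cor)
    out[i, seq_along(ci)] <- ci
  }
  out
}

#' Significance of canonical components across subjects
#'
#' One-sided Wilcoxon signed-rank test, per component, of the subjects'
#' canonical correlations against their matched per-subject surrogate
#' baselines (e.g. the median of row-permuted surrogates).  Testing the
#' raw correlations against zero would be degenerate — they are
#' nonnegative by construction — hence the surrogate baseline.
#'
#' @param cors subjects x components matrix of canonical correlations.
#' @param surrogate subjects x components matrix of matched surrogate
#'   baselines.
#' @return numeric p-value per component.
#' @export
cca_significance <- function(cors, surrogate) {
  cors <- as.matrix(cors); surrogate <- as.matrix(surrogate)
  if (nrow(cors) < 2L) stop("test undefined for a single subject")
  if (!all(dim(cors) == dim(surrogate))) stop("dimension mismatch")
  vapply(seq_len(ncol(cors)), function(j) {
    d <- cors[, j] - surrogate[, j]
    d <- d[abs(d) > 1e-12]            # standard zero-difference drop
    if (length(d) == 0L) return(1)
    suppressWarnings(stats::wilcox.test(d, alternative = "greater")$p.value)
  }, 0)
}

#' Flatten preparation-window occupancies into decoder features
#'
#' One-hot prevalent state per preparation window, flattened to a vector
#' of length windows x states (20 windows x 5 states = 100 in the default
#' configuration).
#'
#' @param occupancies list of states x windows one-hot matrices (from
#'   [epoch_occupancy()] on the preparation windows).
#' @return epochs x (windows*states) numeric matrix.
#' @export
build_feature_vectors <- function(occupancies) {
  t(vapply(occupancies, as.vector,
           numeric(length(occupancies[[1L]]))))
}

# Shrinkage LDA: pooled within-class covariance shrunk toward a scaled
# identity, Sigma_l = (1-lambda) S + lambda (tr(S)/d) I.  Needed because
# one-hot occupancy features on tens of epochs make the pooled covariance
# singular.  Returns linear discriminant functions for equal priors.
shrinkage_lda_fit <- function(X, y, lambda = 0.2) {
  classes <- sort(unique(y))
  d <- ncol(X)
  M <- t(vapply(classes, function(g) colMeans(X[y == g, , drop = FALSE]),
                numeric(d)))
  S <- matrix(0, d, d)
  for (g in classes) {
    Xg <- X[y == g, , drop = FALSE]
    Xg <- sweep(Xg, 2L, colMeans(Xg))
    S <- S + crossprod(Xg)
  }
  S <- S / max(nrow(X) - length(classes), 1L)
  target <- (sum(diag(S)) / d + 1e-8) * diag(d)
  Sl <- (1 - lambda) * S + lambda * target
  Winv <- chol2inv(chol(Sl))
  A <- Winv %*% t(M)                      # d x n_classes
  b <- -0.5 * colSums(t(M) * A)           # intercepts
  list(A = A, b = b, classes = classes)
}

shrinkage_lda_predict <- function(fit, X) {
  scores <- X %*% fit$A + rep(fit$b, each = nrow(X))
  fit$classes[max.col(scores, ties.method = "first")]
}

# one repetition of the decoding protocol; returns confusion counts and
# the fitted coefficient matrices
.lda_rep <- function(features, labels, classes, lambda, shuffle_train = FALSE) {
  d <- ncol(features)
  conf <- matrix(0, length(classes), length(classes))
  coefs <- array(0, dim = c(d, length(classes), length(classes)))
  for (gi in seq_along(classes)) {
    g <- classes[gi]
    idx_g <- which(labels == g)
    n_half <- floor(length(idx_g) / 2)
    tr_g <- sample(idx_g, n_half)
    te_g <- setdiff(idx_g, tr_g)
    tr_o <- unlist(lapply(setdiff(classes, g), function(o)
      sample(which(labels == o), n_half)))
    tr <- c(tr_g, tr_o)
    ytr <- labels[tr]
    if (shuffle_train) ytr <- sample(ytr)
    fit <- shrinkage_lda_fit(features[tr, , drop = FALSE], ytr, lambda)
    pred <- shrinkage_lda_predict(fit, features[te_g, , drop = FALSE])
    conf[gi, ] <- conf[gi, ] + tabulate(match(pred, classes),
                                        nbins = length(classes))
    full <- matrix(0, d, length(classes))
    full[, match(fit$classes, classes)] <- fit$A
    coefs[, , gi] <- full
  }
  list(conf = conf, coefs = apply(coefs, c(1, 2), mean))
}

#' Four-class LDA grasp decoding with repeated half-split cross-validation
#'
#' For each grasp type and repetition: train a four-class shrinkage LDA on
#' half of that grasp's epochs plus an equal number of epochs from each
#' other grasp, test on the held-out epochs of that grasp; the confusion
#' row of a grasp is the distribution of predicted labels (in percent),
#' averaged over repetitions.
#'
#' @param features epochs x d feature matrix (see
#'   [build_feature_vectors()]).
#' @param labels grasp label per epoch (4 classes, >= 4 epochs each).
#' @param n_reps number of split repetitions (default 1000).
#' @param lambda covariance shrinkage intensity in [0, 1].
#' @param seed integer seed (splits are reproducible under it).
#' @return object of class `decoding_result`: `confusion` (rows sum to
#'   100), `accuracy` (per repetition, %), `coef_mean`, `coef_sd`
#'   (over repetitions), `classes`, `n_reps`.
#' @export
lda_decode <- function(features, labels, n_reps = 1000L, lambda = 0.2,
                       seed = 1L) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  counts <- table(labels)
  if (any(counts < 4L)) stop("every class needs at least 4 epochs")
  set.seed(seed)
  d <- ncol(features)
  conf_acc <- matrix(0, length(classes), length(classes))
  acc <- numeric(n_reps)
  cs <- matrix(0, d, length(classes))   # running sums for coef mean/sd
  css <- matrix(0, d, length(classes))
  for (r in seq_len(n_reps)) {
    rep_out <- .lda_rep(features, labels, classes, lambda)
    conf_r <- rep_out$conf / rowSums(rep_out$conf) * 100
    conf_acc <- conf_acc + conf_r
    acc[r] <- mean(diag(conf_r))
    cs <- cs + rep_out$coefs
    css <- css + rep_out$coefs^2
  }
  coef_mean <- cs / n_reps
  coef_sd <- sqrt(pmax(css / n_reps - coef_mean^2, 0))
  conf_acc <- conf_acc / n_reps
  dimnames(conf_acc) <- list(true = classes, predicted = classes)
  structure(list(confusion = conf_acc, accuracy = acc,
                 coef_mean = coef_mean, coef_sd = coef_sd,
                 classes = classes, n_reps = n_reps),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> %d classes, %d reps, mean accuracy %.1f%%\n",
              length(x$classes), x$n_reps, mean(x$accuracy)))
  invisible(x)
}

#' Permutation null of the LDA decoder
#'
#' Repeats the decoding protocol with the training labels randomly
#' shuffled at each repetition; the significance accuracy level is the
#' mean of the null accuracies (~25% for four balanced classes).
#'
#' @inheritParams lda_decode
#' @param n_null number of null repetitions (default 10000; < 100 warns).
#' @param return_coefs also accumulate null coefficient mean/SD ratios
#'   (for [coefficient_stability()]).
#' @return list with `null_accuracy` (vector, %), `significance_level`
#'   (mean, %), and `coef_ratio` when `return_coefs` is TRUE.
#' @export
lda_null <- function(features, labels, n_null = 10000L, lambda = 0.2,
                     seed = 1L, return_coefs = FALSE) {
  if (n_null < 100L) warning("fewer than 100 null repetitions: unstable significance level")
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  set.seed(seed)
  acc <- numeric(n_null)
  cs <- css <- 0
  for (r in seq_len(n_null)) {
    rep_out <- .lda_rep(features, labels, classes, lambda,
                        shuffle_train = TRUE)
    acc[r] <- mean(diag(rep_out$conf / rowSums(rep_out$conf) * 100))
    if (return_coefs) { cs <- cs + rep_out$coefs; css <- css + rep_out$coefs^2 }
  }
  out <- list(null_accuracy = acc, significance_level = mean(acc))
  if (return_coefs) {
    cm <- cs / n_null
    csd <- sqrt(pmax(css / n_null - cm^2, 0))
    out$coef_ratio <- abs(cm) / ifelse(csd == 0, 1, csd)
  }
  out
}

#' Remove the influence of a nuisance feature block by linear regression
#'
#' Regresses each target column on the nuisance block (with intercept) and
#' returns the residuals; used before decoding with only the resting-state
#' or only the task-related microstate occurrences.  Idempotent.
#'
#' @param target epochs x p matrix to be residualized.
#' @param nuisance epochs x q matrix whose influence is removed.
#' @return residual matrix, same shape as `target`.
#' @export
residualize_features <- function(target, nuisance) {
  target <- as.matrix(target); nuisance <- as.matrix(nuisance)
  if (nrow(target) != nrow(nuisance)) stop("row mismatch")
  Z <- cbind(1, nuisance)
  target - Z %*% qr.coef(qr(Z), target)
}

#' Stability of LDA coefficients against a permutation null
#'
#' Per-coefficient mean/SD ratio over the cross-validation repetitions,
#' compared against the 95th percentile of the same ratios under the
#' label-shuffled null.  Coefficients with zero SD get a capped ratio and
#' a flag.
#'
#' @param coef_mean,coef_sd coefficient mean and SD over repetitions (from
#'   [lda_decode()]).
#' @param null_ratios vector or matrix of null mean/SD ratios.
#' @param cap value assigned when SD is zero.
#' @return list with `ratio`, `capped` (logical), `cutoff` (null 95th
#'   percentile) and `significant`.
#' @export
coefficient_stability <- function(coef_mean, coef_sd, null_ratios,
                                  cap = 100) {
  capped <- coef_sd == 0
  ratio <- abs(coef_mean) / ifelse(capped, 1, coef_sd)
  ratio[capped] <- cap
  cutoff <- stats::quantile(abs(null_ratios), 0.95, names = FALSE)
  list(ratio = ratio, capped = capped, cutoff = cutoff,
       significant = ratio > cutoff)
}
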
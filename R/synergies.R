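#' Muscle synergy model
#'
#' Nonnegative factorization `V ~ W %*% H` of an EMG envelope matrix:
#' `W` (muscles x K) holds the synergy weight vectors, stored with
#' unit-norm columns (scale absorbed into the activations `H`).
#'
#' @param W muscles x K nonnegative weight matrix.
#' @param H K x samples nonnegative activation matrix.
#' @param vaf variance accounted for by `W %*% H`.
#' @param restarts_used number of restarts actually run.
#' @param flagged TRUE when the VAF threshold was unreachable.
#' @export
synergy_model <- function(W, H, vaf = NA_real_, restarts_used = NA_integer_,
                          flagged = FALSE) {
  if (any(W < 0) || any(H < 0)) stop("W and H must be nonnegative")
  nrm <- sqrt(colSums(W^2))
  nrm[nrm == 0] <- 1
  W <- sweep(W, 2L, nrm, "/")
  H <- sweep(H, 1L, nrm, "*")
  structure(list(W = W, H = H, vaf = vaf, restarts_used = restarts_used,
                 flagged = flagged),
            class = "synergy_model")
}

#' @export
print.synergy_model <- function(x, ...) {
  cat(sprintf("<synergy_model> K=%d synergies x %d muscles, VAF=%.4f%s\n",
              ncol(x$W), nrow(x$W), x$vaf,
              if (x$flagged) " (threshold unreachable)" else ""))
  invisible(x)
}

#' Variance accounted for by a synergy model
#'
#' Uncentered VAF, `1 - ||V - WH||^2_F / ||V||^2_F`, the standard
#' definition for rectified EMG envelopes.
#'
#' @param V muscles x samples nonnegative matrix.
#' @param model a [synergy_model()], or a list with `W` and `H`.
#' @export
vaf <- function(V, model) {
  R <- V - model$W %*% model$H
  1 - sum(R^2) / sum(V^2)
}

# one multiplicative-update run minimizing squared Frobenius error
nnmf_run <- function(V, K, max_iter, tol) {
  m <- nrow(V); n <- ncol(V)
  W <- matrix(stats::runif(m * K, 0.1, 1), m, K)
  H <- matrix(stats::runif(K * n, 0.1, 1), K, n)
  eps <- 1e-12
  obj_prev <- Inf
  obj_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, V)) / (crossprod(W, W %*% H) + eps)
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
    obj <- sum((V - W %*% H)^2)
    obj_trace <- c(obj_trace, obj)
    if (is.finite(obj_prev) && abs(obj_prev - obj) <= tol * max(obj_prev, eps))
      break
    obj_prev <- obj
  }
  list(W = W, H = H, obj_trace = obj_trace)
}

#' L2-norm non-negative matrix factorization with restart selection
#'
#' Multiplicative-update minimization of the squared Frobenius
#' reconstruction error.  Because the problem is non-convex, the
#' factorization is repeated `n_restarts` times from random starts and the
#' solution explaining the most EMG variance is kept.
#'
#' @param V muscles x samples nonnegative matrix.
#' @param K number of synergies (1 <= K <= min(dim(V))).
#' @param n_restarts number of random restarts (default 50).
#' @param max_iter iteration cap per restart.
#' @param tol relative objective-change tolerance.
#' @param seed integer seed.
#' @return a [synergy_model()]; the objective trace of the winning restart
#'   is attached as attribute `"obj_trace"` (non-increasing by
#'   construction of the updates).
#' @export
nnmf <- function(V, K, n_restarts = 50L, max_iter = 500L, tol = 1e-6,
                 seed = 1L) {
  V <- as.matrix(V)
  if (any(V < 0)) stop("V must be nonnegative")
  if (K < 1L || K > min(dim(V))) stop("K must be in [1, min(dim(V))]")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    run <- nnmf_run(V, K, max_iter, tol)
    v <- vaf(V, run)
    if (is.null(best) || v > best$vaf)
      best <- list(W = run$W, H = run$H, vaf = v, obj_trace = run$obj_trace)
  }
  out <- synergy_model(best$W, best$H, vaf = best$vaf,
                       restarts_used = n_restarts)
  attr(out, "obj_trace") <- best$obj_trace
  out
}

#' Select the number of synergies by the VAF threshold
#'
#' Returns the model at the smallest K whose variance accounted for
#' exceeds `threshold` (default 98%); if no K up to `k_max` reaches it,
#' the `k_max` model is returned with `flagged = TRUE`.
#'
#' @inheritParams nnmf
#' @param k_max largest model order to try.
#' @param threshold VAF threshold (fraction).
#' @export
select_n_synergies <- function(V, k_max, threshold = 0.98, n_restarts = 50L,
                               max_iter = 500L, tol = 1e-6, seed = 1L) {
  last <- NULL
  for (K in seq_len(k_max)) {
    m <- nnmf(V, K, n_restarts = n_restarts, max_iter = max_iter, tol = tol,
              seed = seed + K)
    last <- m
    if (m$vaf > threshold) return(m)
  }
  warning(sprintf("VAF threshold %.2f unreachable at k_max=%d", threshold,
                  k_max))
  last$flagged <- TRUE
  last
}

#' Match synergy weight vectors to a reference set
#'
#' Similarity is the normalized scalar product (DOT, cosine similarity)
#' between weight vectors; the optimal one-to-one assignment maximizing
#' the summed DOT is found exhaustively, and pairs below `dot_threshold`
#' are reported dissimilar (unmatched).
#'
#' @param W muscles x K weight matrix (columns are synergies).
#' @param reference muscles x Kref reference weight matrix.
#' @param dot_threshold dissimilarity threshold (default 0.65).
#' @return list with `mapping` (data.frame: synergy, ref, dot, matched),
#'   `unmatched`, and the full DOT table.
#' @export
match_synergies <- function(W, reference, dot_threshold = 0.65) {
  nw <- sweep(W, 2L, pmax(sqrt(colSums(W^2)), 1e-12), "/")
  nr <- sweep(reference, 2L, pmax(sqrt(colSums(reference^2)), 1e-12), "/")
  dot <- crossprod(nw, nr)                # K x Kref
  swap <- ncol(nw) > ncol(nr)
  a <- assign_optimal(if (swap) t(dot) else dot)
  if (swap) {
    mapping <- data.frame(synergy = a, ref = seq_len(ncol(nr)))
  } else {
    mapping <- data.frame(synergy = seq_len(ncol(nw)), ref = a)
  }
  mapping$dot <- dot[cbind(mapping$synergy, mapping$ref)]
  mapping$matched <- mapping$dot >= dot_threshold
  unmatched <- sort(c(mapping$synergy[!mapping$matched],
                      setdiff(seq_len(ncol(nw)), mapping$synergy)))
  list(mapping = mapping, unmatched = unmatched, dot = dot)
}

#' Build reference synergies across subjects
#'
#' Pools the (unit-normalized) synergy weight vectors of all subjects and
#' groups them by agglomerative hierarchical clustering on the Minkowski
#' distance (order 2 by default, average linkage); the renormalized
#' cluster means, with the tree cut at `k`, are the reference synergies.
#'
#' @param W_list list of muscles x K weight matrices (one per
#'   subject/condition).
#' @param k number of reference synergies (tree cut).
#' @param minkowski_order Minkowski distance order.
#' @return list with `reference` (muscles x k matrix), `cluster`
#'   (per-pooled-synergy cluster index) and the `hclust` tree.
#' @export
build_reference_set <- function(W_list, k, minkowski_order = 2) {
  pooled <- do.call(cbind, W_list)
  pooled <- sweep(pooled, 2L, pmax(sqrt(colSums(pooled^2)), 1e-12), "/")
  if (ncol(pooled) < k) stop("fewer pooled synergies than requested clusters")
  if (ncol(pooled) == 1L) {
    return(list(reference = pooled, cluster = 1L, tree = NULL))
  }
  d <- stats::dist(t(pooled), method = "minkowski", p = minkowski_order)
  tree <- stats::hclust(d, method = "average")
  cl <- stats::cutree(tree, k = k)
  ref <- vapply(seq_len(k), function(j)
    rowMeans(pooled[, cl == j, drop = FALSE]), numeric(nrow(pooled)))
  ref <- sweep(ref, 2L, pmax(sqrt(colSums(ref^2)), 1e-12), "/")
  list(reference = ref, cluster = cl, tree = tree)
}

#' Window-wise temporal occurrence of synergies
#'
#' For each synergy k and time window: the Pearson correlation between the
#' vectorized putative EMG (`w_k %o% h_k` restricted to the window) and
#' the vectorized observed EMG in that window, averaged over epochs.
#' Zero-variance windows yield 0 (logged via attribute `"degenerate"`).
#'
#' @param model a [synergy_model()] fit to the pooled epochs.
#' @param epochs list of muscles x samples EMG matrices, all aligned to
#'   the same timeline as the columns of `model$H` (the model `H` is
#'   recycled per epoch when it spans exactly one epoch).
#' @param grid window grid from [window_grid()] (or any data.frame with
#'   `start`/`end` in seconds relative to the epoch start).
#' @param rate sampling rate of the epochs in Hz.
#' @return an [occurrence_matrix()] with values = mean correlations
#'   (synergies x windows).
#' @export
synergy_occurrence <- function(model, epochs, grid, rate) {
  K <- ncol(model$W)
  n_win <- nrow(grid)
  acc <- matrix(0, K, n_win)
  degen <- matrix(0L, K, n_win)
  n_ep <- length(epochs)
  len1 <- ncol(epochs[[1L]])
  for (e in seq_len(n_ep)) {
    V <- epochs[[e]]
    h_off <- (e - 1L) * len1
    use_off <- ncol(model$H) >= h_off + ncol(V)
    for (w in seq_len(n_win)) {
      i0 <- floor(grid$start[w] * rate) + 1L
      i1 <- min(floor(grid$end[w] * rate), ncol(V))
      if (i1 < i0) { degen[, w] <- degen[, w] + 1L; next }
      idx <- i0:i1
      hidx <- if (use_off) h_off + idx else idx
      for (k in seq_len(K)) {
        put <- as.vector(model$W[, k] %o% model$H[k, hidx])
        obs <- as.vector(V[, idx])
        if (stats::sd(put) == 0 || stats::sd(obs) == 0) {
          degen[k, w] <- degen[k, w] + 1L
        } else {
          acc[k, w] <- acc[k, w] + stats::cor(put, obs)
        }
      }
    }
  }
  vals <- acc / pmax(n_ep - degen, 1L)
  out <- occurrence_matrix(vals, grid, n_epochs = n_ep, kind = "synergy")
  attr(out, "degenerate") <- degen
  out
}
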
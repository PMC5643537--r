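# Shared fixtures, built in code at test time.

# small ground truth with default study-condition parameters
tiny_truth <- function(seed = 1L, ...) ground_truth(seed = seed, ...)

# a microstate_set holding the true topographies (optionally a subset)
truth_msset <- function(truth, states = seq_along(truth$topographies)) {
  microstate_set(t(do.call(cbind, truth$topographies[states])))
}

# random one-hot occupancy matrices (states x windows) for n epochs
random_occupancies <- function(n_epochs, n_states, n_windows,
                               probs = rep(1, n_states)) {
  lapply(seq_len(n_epochs), function(i) {
    m <- matrix(0, n_states, n_windows)
    m[cbind(sample.int(n_states, n_windows, TRUE, prob = probs),
            seq_len(n_windows))] <- 1
    m
  })
}

# brute-force best 2-partition objective for polarity-invariant k-means:
# for each partition, the optimal template of a cluster is the dominant
# eigenvector of the member outer-product sum, so the attained objective
# is the sum of leading eigenvalues
best_partition_objective <- function(X, K = 2L) {
  stopifnot(K == 2L)
  n <- nrow(X)
  best <- -Inf
  for (code in 1:(2^(n - 1L) - 1L)) {
    grp <- as.integer(intToBits(code)[1:n]) + 1L
    if (length(unique(grp)) < K) next
    obj <- sum(vapply(1:K, function(k) {
      M <- X[grp == k, , drop = FALSE]
      max(eigen(crossprod(M), symmetric = TRUE, only.values = TRUE)$values)
    }, 0))
    best <- max(best, obj)
  }
  best
}
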
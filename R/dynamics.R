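#' Occurrence matrix container
#'
#' States (or synergies) x windows values in [0, 1] on a fixed window
#' grid.
#'
#' @param values states x windows numeric matrix.
#' @param grid data.frame with `start`, `end` (seconds) and `phase` per
#'   window; windows must be ordered and non-overlapping.
#' @param n_epochs number of epochs the values were computed from.
#' @param kind `"microstate"` or `"synergy"`.
#' @export
occurrence_matrix <- function(values, grid, n_epochs = NA_integer_,
                              kind = "microstate") {
  values <- as.matrix(values)
  if (nrow(grid) != ncol(values)) stop("grid/window count mismatch")
  if (is.unsorted(grid$start) || any(grid$end[-nrow(grid)] > grid$start[-1] + 1e-9))
    stop("window grid must be ordered and non-overlapping")
  structure(list(values = values, grid = grid, n_epochs = n_epochs,
                 kind = kind),
            class = "occurrence_matrix")
}

#' @export
print.occurrence_matrix <- function(x, ...) {
  cat(sprintf("<occurrence_matrix> %s: %d x %d windows (%d epochs), span [%.2f, %.2f] s\n",
              x$kind, nrow(x$values), ncol(x$values), x$n_epochs,
              min(x$grid$start), max(x$grid$end)))
  invisible(x)
}

#' Plot an occurrence matrix
#'
#' Basic red-scale image of states x windows occurrence values.
#' @param x an [occurrence_matrix()].
#' @param ... passed to [graphics::image()].
#' @export
plot.occurrence_matrix <- function(x, ...) {
  graphics::image(x = (x$grid$start + x$grid$end) / 2,
                  y = seq_len(nrow(x$values)), z = t(x$values),
                  col = grDevices::hcl.colors(64, "Reds", rev = TRUE),
                  xlab = "time (s)", ylab = x$kind, ...)
  invisible(x)
}

#' Trial-timeline window grid
#'
#' 20 windows of 100 ms for movement preparation (-2 s to movement onset),
#' 10 windows of 10% of the movement duration for movement execution, and
#' 20 windows of 100 ms for the holding phase.  Times are in seconds
#' relative to movement onset.
#'
#' @param prep_s preparation span (default 2 s).
#' @param move_s movement duration in seconds (task mean).
#' @param hold_s holding span (default 2 s).
#' @return data.frame with `start`, `end`, `phase`.
#' @export
window_grid <- function(prep_s = 2, move_s = 1, hold_s = 2) {
  prep <- data.frame(start = seq(-prep_s, -0.1, by = 0.1),
                     end = seq(-prep_s + 0.1, 0, by = 0.1),
                     phase = "preparation")
  move <- data.frame(start = move_s * seq(0, 0.9, by = 0.1),
                     end = move_s * seq(0.1, 1, by = 0.1),
                     phase = "execution")
  hold <- data.frame(start = move_s + seq(0, hold_s - 0.1, by = 0.1),
                     end = move_s + seq(0.1, hold_s, by = 0.1),
                     phase = "holding")
  rbind(prep, move, hold)
}

#' Per-window prevalent state of one epoch
#'
#' Assigns each window the state with the most samples in it.  Ties go to
#' the previous window's winner when it is among the tied states, and are
#' otherwise broken at random among the tied states (reproducible under
#' the session RNG seed).
#'
#' @param seg a [segmentation()] covering the grid span.
#' @param grid window grid from [window_grid()].
#' @param n_states number of states.
#' @param t0 time (seconds, on the grid's clock) of the first sample of
#'   the segmentation; e.g. `-2` for an epoch starting 2 s before
#'   movement onset.
#' @return states x windows one-hot matrix.
#' @export
epoch_occupancy <- function(seg, grid, n_states, t0 = min(grid$start)) {
  rate <- seg$rate
  n <- length(seg$labels)
  onehot <- matrix(0, n_states, nrow(grid))
  prev <- NA_integer_
  for (w in seq_len(nrow(grid))) {
    i0 <- floor((grid$start[w] - t0) * rate) + 1L
    i1 <- min(floor((grid$end[w] - t0) * rate + 1e-9), n)
    if (i1 < i0) stop(sprintf("window %d empty: segmentation does not cover the grid", w))
    counts <- tabulate(seg$labels[i0:i1], nbins = n_states)
    top <- which(counts == max(counts))
    win <- if (length(top) == 1L) top
           else if (!is.na(prev) && prev %in% top) prev
           else top[sample.int(length(top), 1L)]
    onehot[win, w] <- 1
    prev <- win
  }
  onehot
}

#' Occurrence histogram across epochs
#'
#' Fraction of epochs in which each state is the prevalent one per window;
#' column sums are exactly 1 when built from one-hot epoch occupancies.
#'
#' @param occupancies list of states x windows one-hot matrices (from
#'   [epoch_occupancy()]).
#' @param grid the shared window grid.
#' @return an [occurrence_matrix()].
#' @export
occurrence_histogram <- function(occupancies, grid) {
  if (length(occupancies) == 0L) stop("no epochs")
  vals <- Reduce(`+`, occupancies) / length(occupancies)
  occurrence_matrix(vals, grid, n_epochs = length(occupancies),
                    kind = "microstate")
}

#' Permutation test on occurrence values between two conditions
#'
#' Statistic: difference of per-state/per-window mean occurrence between
#' conditions.  The null exchanges condition labels at the epoch level
#' (preserving within-epoch dependence across windows and states); the
#' two-sided threshold is the (1 - alpha) quantile of the absolute null
#' statistic per cell.
#'
#' @param occ_a,occ_b lists of states x windows epoch occupancy matrices.
#' @param n_perm number of permutations.
#' @param alpha significance level (requires `n_perm >= 1/alpha`).
#' @param seed integer seed.
#' @return list with `diff` (observed difference), `p` (two-sided
#'   permutation p-values), `threshold` (per-cell absolute threshold) and
#'   `significant` (logical matrix).
#' @export
permutation_test <- function(occ_a, occ_b, n_perm = 10000L, alpha = 0.05,
                             seed = 1L) {
  if (n_perm < 1 / alpha) stop("n_perm too small for the requested alpha")
  da <- dim(occ_a[[1L]])
  if (!identical(da, dim(occ_b[[1L]]))) stop("mismatched occurrence grids")
  na <- length(occ_a); nb <- length(occ_b)
  # flatten epochs to rows for fast permutation
  M <- t(vapply(c(occ_a, occ_b), as.vector, numeric(prod(da))))
  obs <- colMeans(M[seq_len(na), , drop = FALSE]) -
    colMeans(M[na + seq_len(nb), , drop = FALSE])
  set.seed(seed)
  null_abs <- matrix(0, n_perm, ncol(M))
  for (p in seq_len(n_perm)) {
    idx <- sample.int(na + nb)
    null_abs[p, ] <- abs(colMeans(M[idx[seq_len(na)], , drop = FALSE]) -
                           colMeans(M[idx[na + seq_len(nb)], , drop = FALSE]))
  }
  pvals <- (colSums(null_abs >= rep(abs(obs), each = n_perm) - 1e-12) + 1) /
    (n_perm + 1)
  thr <- apply(null_abs, 2L, stats::quantile, probs = 1 - alpha, names = FALSE)
  shape <- function(v) matrix(v, da[1L], da[2L])
  list(diff = shape(obs), p = shape(pvals), threshold = shape(thr),
       significant = shape(pvals <= alpha))
}
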
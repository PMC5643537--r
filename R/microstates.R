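#' Global field power
#'
#' Spatial standard deviation of the scalp map at each time sample
#' (population SD around the per-sample channel mean).  Peaks of the GFP
#' mark moments of maximal topographic signal and are the samples used for
#' clustering.
#'
#' @param x channels x samples numeric matrix (>= 2 channels).
#' @return numeric vector, one nonnegative value per sample.
#' @export
gfp <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("gfp needs at least 2 channels")
  mu <- colMeans(x)
  sqrt(colMeans(x^2) - mu^2)
}

#' Strict local maxima of a GFP series
#'
#' @param g numeric vector (length >= 3).
#' @return integer indices of strict local maxima (possibly empty).
#' @export
find_gfp_peaks <- function(g) {
  if (length(g) < 3L) stop("series too short for peak detection")
  i <- 2:(length(g) - 1L)
  i[g[i] > g[i - 1L] & g[i] > g[i + 1L]]
}

#' Set of microstate template maps
#'
#' @param maps K x channels matrix of templates; rows are stored
#'   average-referenced with unit norm.
#' @param labels template labels.
#' @param subject,condition provenance tags.
#' @param cv_value cross-validation criterion value at this K (or NA).
#' @param ev explained variance of the segmentation that produced the set.
#' @export
microstate_set <- function(maps, labels = NULL, subject = NA, condition = NA,
                           cv_value = NA_real_, ev = NA_real_) {
  maps <- as.matrix(maps)
  maps <- maps - rowMeans(maps)
  nrm <- sqrt(rowSums(maps^2))
  if (any(nrm == 0)) stop("degenerate (constant) template map")
  maps <- maps / nrm
  if (is.null(labels)) labels <- paste0("MS", seq_len(nrow(maps)))
  structure(list(maps = maps, labels = labels, subject = subject,
                 condition = condition, cv_value = cv_value, ev = ev),
            class = "microstate_set")
}

#' @export
print.microstate_set <- function(x, ...) {
  cat(sprintf("<microstate_set> K=%d maps x %d channels (subject=%s, condition=%s, CV=%.4g, EV=%.3f)\n",
              nrow(x$maps), ncol(x$maps), x$subject, x$condition,
              x$cv_value, x$ev))
  invisible(x)
}

# normalize rows of a sample x channel matrix to zero mean, unit norm;
# drops nothing (zero rows raise an error upstream where relevant)
normalize_maps <- function(X) {
  X <- X - rowMeans(X)
  nrm <- sqrt(rowSums(X^2))
  nrm[nrm == 0] <- 1
  X / nrm
}

# polarity-invariant centroid: dominant eigenvector of the sum of outer
# products of the member maps = first right singular vector of the stacked
# member matrix
dominant_map <- function(X) {
  if (nrow(X) == 1L) return(X[1L, ] / sqrt(sum(X[1L, ]^2)))
  sv <- svd(X, nu = 0L, nv = 1L)
  v <- sv$v[, 1L]
  v / sqrt(sum(v^2))
}

#' Polarity-invariant topographic k-means
#'
#' Modified spatial k-means clustering of scalp maps in which a map and its
#' sign-flip are the same state: samples are assigned to the template with
#' the highest squared spatial correlation, and each template is updated as
#' the dominant eigenvector of the outer-product sum of its member maps.
#' The best of `n_init` random restarts by explained variance is returned.
#'
#' @param X samples x channels matrix of (average-referenced) maps.
#' @param K number of clusters (<= number of distinct maps).
#' @param n_init number of random restarts.
#' @param seed integer seed (restarts are deterministic under it).
#' @param max_iter iteration cap per restart.
#' @return list with `msset` (a [microstate_set()]), `assignment`
#'   (per-sample cluster index), `ev` (explained variance in [0,1]) and
#'   `converged`.
#' @export
modified_kmeans <- function(X, K, n_init = 10L, seed = 1L, max_iter = 100L) {
  X <- normalize_maps(as.matrix(X))
  n <- nrow(X)
  if (n < K) stop("fewer maps than clusters")
  if (nrow(unique(round(X, 10))) < K)
    stop("K exceeds the number of distinct maps")
  set.seed(seed)
  best <- NULL
  for (init in seq_len(n_init)) {
    Tm <- X[sample.int(n, K), , drop = FALSE]
    assign_prev <- rep(0L, n)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      C2 <- (X %*% t(Tm))^2                 # squared correlations
      a <- max.col(C2, ties.method = "first")
      if (identical(a, assign_prev)) { converged <- TRUE; break }
      assign_prev <- a
      for (k in seq_len(K)) {
        member <- which(a == k)
        if (length(member) == 0L) {
          # re-seed empty cluster at the worst-fit map
          worst <- which.min(C2[cbind(seq_len(n), a)])
          Tm[k, ] <- X[worst, ]
        } else {
          Tm[k, ] <- dominant_map(X[member, , drop = FALSE])
        }
      }
    }
    ev <- sum((X %*% t(Tm))[cbind(seq_len(n), assign_prev)]^2) / n
    if (is.null(best) || ev > best$ev)
      best <- list(Tm = Tm, assignment = assign_prev, ev = ev,
                   converged = converged)
  }
  if (!best$converged)
    warning("modified_kmeans: not converged within max_iter; returning best-so-far")
  list(msset = microstate_set(best$Tm, ev = best$ev),
       assignment = best$assignment, ev = best$ev,
       converged = best$converged)
}

#' Cross-validation criterion for microstate model order
#'
#' `CV = sigma2 * ((C - 1)/(C - 1 - K))^2`, where `sigma2` is the mean
#' residual variance of the maps after projection onto their assigned
#' unit-norm template and `C` is the channel count.  Only the location of
#' the minimum over K is consumed downstream, which is invariant to
#' constant rescaling of the criterion.
#'
#' @param X samples x channels matrix of maps (will be average-referenced).
#' @param msset a [microstate_set()].
#' @param assignment optional per-sample template index; recomputed by
#'   squared-correlation argmax when missing.
#' @return scalar criterion value.
#' @export
cv_criterion <- function(X, msset, assignment = NULL) {
  X <- as.matrix(X)
  X <- X - rowMeans(X)
  C <- ncol(X)
  K <- nrow(msset$maps)
  if (K >= C - 1L) stop("criterion undefined for K >= channels - 1")
  proj <- X %*% t(msset$maps)             # samples x K inner products
  if (is.null(assignment)) assignment <- max.col(proj^2, ties.method = "first")
  a2 <- proj[cbind(seq_len(nrow(X)), assignment)]^2
  sigma2 <- mean((rowSums(X^2) - a2) / (C - 1L))
  sigma2 * ((C - 1L) / (C - 1L - K))^2
}

#' Select the number of microstates by the CV minimum
#'
#' Runs [modified_kmeans()] for each K in `k_range` on the supplied maps
#' (typically maps at GFP peaks) and returns the set at the absolute
#' minimum of the cross-validation criterion; ties break toward smaller K.
#'
#' @param X samples x channels matrix of maps.
#' @param k_range candidate model orders.
#' @param n_init restarts per K.
#' @param seed integer seed.
#' @return a [microstate_set()] with `cv_value` filled in; the full CV
#'   curve is attached as attribute `"cv_curve"`.
#' @export
select_k <- function(X, k_range = 2:8, n_init = 10L, seed = 1L) {
  if (length(k_range) == 0L) stop("empty k_range")
  X <- normalize_maps(as.matrix(X))
  cv <- rep(NA_real_, length(k_range))
  fits <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    fit <- modified_kmeans(X, k_range[i], n_init = n_init, seed = seed + i)
    cv[i] <- cv_criterion(X, fit$msset, fit$assignment)
    fits[[i]] <- fit
  }
  best <- which(cv <= min(cv) + 1e-12)[1L]   # tie -> smaller K
  out <- fits[[best]]$msset
  out$cv_value <- cv[best]
  attr(out, "cv_curve") <- data.frame(K = k_range, cv = cv)
  out
}

#' Per-sample microstate segmentation
#'
#' @param labels per-sample state indices.
#' @param gfp per-sample global field power.
#' @param rate sampling rate in Hz.
#' @param corr optional samples x K absolute-correlation matrix from
#'   back-fitting (used by [smooth_segmentation()]).
#' @export
segmentation <- function(labels, gfp, rate, corr = NULL) {
  structure(list(labels = as.integer(labels), gfp = gfp, rate = rate,
                 corr = corr, segments = label_runs(as.integer(labels))),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> %d samples @ %g Hz, %d states, %d segments\n",
              length(x$labels), x$rate, length(unique(x$labels)),
              nrow(x$segments)))
  invisible(x)
}

#' Back-fit microstate templates to a recording
#'
#' Labels every sample with the template of highest absolute spatial
#' correlation (polarity ignored).  Zero-variance samples carry the label
#' of the previous sample (the leading run of such samples, if any, takes
#' the first valid label).
#'
#' @param rec a [recording] (EEG) with channel count matching the templates.
#' @param msset a [microstate_set()].
#' @return a [segmentation()].
#' @export
backfit <- function(rec, msset) {
  X <- rec$data
  if (nrow(X) != ncol(msset$maps)) stop("channel count mismatch")
  Xc <- X - rep(colMeans(X), each = nrow(X))
  nrm <- sqrt(colSums(Xc^2))
  g <- gfp(X)
  A <- abs(t(msset$maps %*% Xc))          # samples x K, |inner products|
  ok <- nrm > 0
  A[ok, ] <- A[ok, ] / nrm[ok]
  labels <- max.col(A, ties.method = "first")
  if (any(!ok)) {
    bad <- which(!ok)
    first_ok <- which(ok)[1L]
    if (is.na(first_ok)) stop("all samples have zero variance")
    for (i in bad) labels[i] <- if (i > 1L) labels[i - 1L] else labels[first_ok]
    A[bad, ] <- 0
  }
  segmentation(labels, g, rec$rate, corr = A)
}

#' Reject microstate segments shorter than a minimum duration
#'
#' Segments shorter than `min_dur_ms` are absorbed sample-by-sample into
#' the neighboring state with the higher template correlation (using the
#' correlation matrix stored by [backfit()]); without stored correlations
#' a short run is merged wholly into its longer neighbor.  The returned
#' segmentation contains no run shorter than
#' `ceiling(min_dur_ms * rate / 1000)` samples.
#'
#' @param seg a [segmentation()].
#' @param min_dur_ms minimum segment duration in ms (default 23).
#' @param rate sampling rate; defaults to `seg$rate`.
#' @return a smoothed [segmentation()].
#' @export
smooth_segmentation <- function(seg, min_dur_ms = 23, rate = seg$rate) {
  if (rate <= 0) stop("rate must be positive")
  min_smp <- ceiling(min_dur_ms * rate / 1000)
  labels <- seg$labels
  if (length(labels) < min_smp)
    stop("recording shorter than the minimum segment duration")
  corr <- seg$corr
  repeat {
    # each pass removes at least one run, so this terminates
    runs <- label_runs(labels)
    lens <- runs$end - runs$start
    short <- which(lens < min_smp)
    if (nrow(runs) == 1L || length(short) == 0L) break
    i <- short[which.min(lens[short])]
    left <- if (i > 1L) runs$state[i - 1L] else NA_integer_
    right <- if (i < nrow(runs)) runs$state[i + 1L] else NA_integer_
    idx <- runs$start[i]:(runs$end[i] - 1L)
    if (is.na(left)) {
      labels[idx] <- right
    } else if (is.na(right)) {
      labels[idx] <- left
    } else if (!is.null(corr)) {
      pick <- ifelse(corr[idx, left] >= corr[idx, right], left, right)
      # keep the run contiguous: left-choices must precede right-choices
      nleft <- sum(cumprod(pick == left))
      labels[idx] <- c(rep(left, nleft), rep(right, length(idx) - nleft))
    } else {
      lel <- lens[i - 1L]; ril <- lens[i + 1L]
      labels[idx] <- if (lel >= ril) left else right
    }
  }
  segmentation(labels, seg$gfp, rate, corr = corr)
}

#' Match one microstate set to a reference set
#'
#' Optimal one-to-one assignment (exhaustive over permutations) maximizing
#' the total absolute spatial Pearson correlation; pairs whose correlation
#' falls below `threshold` are reported unmatched.
#'
#' @param msset,reference [microstate_set()] objects.
#' @param threshold correlation threshold below which a pair is reported
#'   unmatched (default 0.65).
#' @return list with `mapping` (data.frame: map, ref, corr, matched),
#'   `unmatched` (indices into `msset`), and the full correlation table.
#' @export
match_sets <- function(msset, reference, threshold = 0.65) {
  A <- msset$maps; B <- reference$maps
  if (nrow(A) == 0L || nrow(B) == 0L) stop("empty microstate set")
  corr <- abs(A %*% t(B))                 # rows zero-mean unit-norm
  swap <- nrow(A) > nrow(B)
  sc <- if (swap) t(corr) else corr
  a <- assign_optimal(sc)
  if (swap) {
    mapping <- data.frame(map = a, ref = seq_len(nrow(B)))
  } else {
    mapping <- data.frame(map = seq_len(nrow(A)), ref = a)
  }
  mapping$corr <- corr[cbind(mapping$map, mapping$ref)]
  mapping$matched <- mapping$corr >= threshold
  unmatched <- sort(c(mapping$map[!mapping$matched],
                      setdiff(seq_len(nrow(A)), mapping$map)))
  list(mapping = mapping, unmatched = unmatched, corr = corr)
}

#' Group-level clustering of subject microstate sets
#'
#' Second-level k-means across subjects with the restriction that each
#' subject's maps go to different clusters: alternate between assigning
#' every subject's maps to clusters by optimal one-to-one assignment
#' (maximizing total absolute correlation) and recomputing each cluster
#' template as the dominant eigenvector of its member maps.
#'
#' @param sets list of [microstate_set()] objects (each with <= K maps).
#' @param K number of group clusters.
#' @param max_iter iteration cap.
#' @param seed seed for the initial template draw.
#' @return list with `templates` (a [microstate_set()]), `mapping` (list of
#'   per-subject cluster index vectors) and `consistency` (mean absolute
#'   correlation between member maps and their cluster template).
#' @export
group_cluster <- function(sets, K, max_iter = 50L, seed = 1L) {
  ns <- vapply(sets, function(s) nrow(s$maps), 1L)
  if (any(ns > K)) stop("K smaller than some subject's map count")
  set.seed(seed)
  donor <- which.max(ns)[1L]
  Tm <- sets[[donor]]$maps
  if (nrow(Tm) < K) {
    extra <- matrix(stats::rnorm((K - nrow(Tm)) * ncol(Tm)), ncol = ncol(Tm))
    Tm <- rbind(Tm, normalize_maps(extra))
  }
  mapping_prev <- NULL
  for (it in seq_len(max_iter)) {
    mapping <- lapply(sets, function(s)
      assign_optimal(abs(s$maps %*% t(Tm))))
    if (identical(mapping, mapping_prev)) break
    mapping_prev <- mapping
    for (k in seq_len(K)) {
      members <- do.call(rbind, Map(function(s, m) {
        i <- which(m == k)
        if (length(i)) s$maps[i, , drop = FALSE] else NULL
      }, sets, mapping))
      if (!is.null(members) && nrow(members) > 0L)
        Tm[k, ] <- dominant_map(members)
    }
  }
  cons <- mean(unlist(Map(function(s, m)
    abs(s$maps %*% t(Tm))[cbind(seq_along(m), m)], sets, mapping_prev)))
  list(templates = microstate_set(Tm, condition = "group"),
       mapping = mapping_prev, consistency = cons)
}

#' Temporal statistics of a segmentation
#'
#' @param seg a [segmentation()].
#' @param n_states number of states (defaults to the max label).
#' @return data.frame with per-state mean segment duration (ms), coverage
#'   fraction and occurrence rate (segments per second).
#' @export
temporal_stats <- function(seg, n_states = max(seg$labels)) {
  runs <- seg$segments
  total_s <- length(seg$labels) / seg$rate
  out <- data.frame(state = seq_len(n_states), mean_duration_ms = 0,
                    coverage = 0, occurrences_per_s = 0)
  for (s in seq_len(n_states)) {
    r <- runs[runs$state == s, , drop = FALSE]
    if (nrow(r) == 0L) next
    lens <- r$end - r$start
    out$mean_duration_ms[s] <- mean(lens) / seg$rate * 1000
    out$coverage[s] <- sum(lens) / length(seg$labels)
    out$occurrences_per_s[s] <- nrow(r) / total_s
  }
  out
}
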
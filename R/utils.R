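#' @keywords internal
"_PACKAGE"

# All permutations of 1..n (n small; used by the exhaustive assignment solver).
permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    out[rows, -1L] <- matrix(setdiff(seq_len(n), i)[sub], nrow(sub))
  }
  out
}

#' Optimal one-to-one assignment maximizing total score
#'
#' Exhaustive search over permutations; the assignment problems in this
#' pipeline (microstate/synergy matching, group clustering) never exceed
#' ~8 items per side, where exhaustive search is exact and instantaneous.
#'
#' @param score matrix (n x m) of pairwise scores; n <= m required.
#' @return integer vector of length n: column assigned to each row.
#' @keywords internal
assign_optimal <- function(score) {
  n <- nrow(score); m <- ncol(score)
  if (n > m) stop("assign_optimal: need nrow <= ncol")
  if (m > 9L) stop("assign_optimal: problem too large for exhaustive search")
  perms <- permutations(m)
  best <- -Inf; best_assign <- NULL
  for (i in seq_len(nrow(perms))) {
    a <- perms[i, seq_len(n)]
    s <- sum(score[cbind(seq_len(n), a)])
    if (s > best + 1e-15) { best <- s; best_assign <- a }
  }
  best_assign
}

# Butterworth design in second-order sections (biquads).  High-order
# Butterworth filters with low normalized cutoffs are numerically unstable
# as single transfer functions; the cascade form is the standard remedy.
# W is the normalized cutoff in (0, 1) (1 = Nyquist).
butter_sos <- function(n, W, type = c("low", "high")) {
  type <- match.arg(type)
  wc <- tan(pi * W / 2)                       # bilinear prewarp
  theta <- pi * (2 * seq_len(n) + n - 1) / (2 * n)
  p <- exp(1i * theta)                        # unit-circle LHP prototype poles
  pairs <- p[Im(p) > 1e-12]
  has_real <- n %% 2L == 1L
  bilinear <- function(b, a) {
    # quadratic (length 3, s^2 s 1) or linear (length 2) section,
    # s = (1 - z^-1)/(1 + z^-1)
    if (length(b) == 3L) {
      num <- c(b[1] + b[2] + b[3], -2 * b[1] + 2 * b[3], b[1] - b[2] + b[3])
      den <- c(a[1] + a[2] + a[3], -2 * a[1] + 2 * a[3], a[1] - a[2] + a[3])
    } else {
      num <- c(b[1] + b[2], b[2] - b[1])
      den <- c(a[1] + a[2], a[2] - a[1])
    }
    list(b = num / den[1], a = den / den[1])
  }
  secs <- lapply(pairs, function(pk) {
    c1 <- -2 * Re(pk)
    if (type == "low") bilinear(c(0, 0, wc^2), c(1, c1 * wc, wc^2))
    else bilinear(c(1, 0, 0), c(1, c1 * wc, wc^2))
  })
  if (has_real) {
    secs <- c(secs, list(
      if (type == "low") bilinear(c(0, wc), c(1, wc))
      else bilinear(c(1, 0), c(1, wc))))
  }
  secs
}

# zero-phase filtering through a cascade of biquads
sos_filtfilt <- function(secs, x) {
  for (s in secs)
    x <- signal::filtfilt(signal::Arma(b = s$b, a = s$a), x)
  x
}

# spatial Pearson correlation between two channel vectors (demeans both)
spatial_cor <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

# run-length segments of a label vector: data.frame(start, end, state),
# end exclusive (half-open intervals)
label_runs <- function(labels) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  data.frame(start = c(1L, head(ends, -1L) + 1L), end = ends + 1L,
             state = r$values)
}
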
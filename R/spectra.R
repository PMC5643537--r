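#' Short-time Hamming-window power spectrogram
#'
#' Sliding Hamming windows of `win_ms` (default 200 ms) with `step_ms`
#' steps (default 32 ms); only the 1-40 Hz frequency range is retained.
#' Multichannel input yields one spectrogram per channel.
#'
#' @param x numeric vector (one channel), channels x samples matrix, or a
#'   [recording].
#' @param rate sampling rate in Hz (taken from the recording if given).
#' @param win_ms,step_ms window and step in ms.
#' @param t0 time (s) of the first sample, used for the spectrogram time
#'   axis (e.g. -1.5 for an epoch starting 1.5 s before movement onset).
#' @param fmin,fmax retained frequency range in Hz.
#' @return a `spectrogram` (power: freq bins x steps, with `freqs`,
#'   `times`, `labels`), or a list of them for multichannel input.
#' @export
stft_power <- function(x, rate = NULL, win_ms = 200, step_ms = 32, t0 = 0,
                       fmin = 1, fmax = 40) {
  if (inherits(x, "recording")) { rate <- x$rate; labels <- x$labels; x <- x$data }
  else labels <- NULL
  if (is.matrix(x) && nrow(x) > 1L) {
    specs <- lapply(seq_len(nrow(x)), function(i)
      stft_power(x[i, ], rate, win_ms, step_ms, t0, fmin, fmax))
    names(specs) <- if (!is.null(labels)) labels else paste0("ch", seq_len(nrow(x)))
    return(specs)
  }
  x <- as.vector(x)
  win <- round(win_ms * rate / 1000)
  step <- max(1L, round(step_ms * rate / 1000))
  if (length(x) < win) stop("signal shorter than one analysis window")
  n_steps <- floor((length(x) - win) / step) + 1L
  h <- 0.54 - 0.46 * cos(2 * pi * seq(0, win - 1) / (win - 1))
  freqs <- (seq_len(win) - 1L) * rate / win
  keep <- which(freqs >= fmin & freqs <= fmax)
  P <- matrix(0, length(keep), n_steps)
  for (s in seq_len(n_steps)) {
    seg <- x[(s - 1L) * step + seq_len(win)] * h
    P[, s] <- abs(stats::fft(seg))[keep]^2
  }
  times <- t0 + ((seq_len(n_steps) - 1L) * step + (win - 1) / 2) / rate
  structure(list(power = P, freqs = freqs[keep], times = times,
                 win_ms = win_ms, step_ms = step_ms, normalized = FALSE),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d bins (%.1f-%.1f Hz) x %d steps, t=[%.2f, %.2f] s%s\n",
              nrow(x$power), min(x$freqs), max(x$freqs), ncol(x$power),
              min(x$times), max(x$times),
              if (x$normalized) ", % change" else ""))
  invisible(x)
}

#' Normalize a spectrogram per frequency bin
#'
#' Each bin is expressed as percent change relative to its own time-mean:
#' `100 * (P(t, f) / mean_t P(t, f) - 1)`; a time-constant bin maps to 0%
#' everywhere.
#'
#' @param spec a `spectrogram` from [stft_power()].
#' @export
normalize_spectrogram <- function(spec) {
  if (spec$normalized) return(spec)
  mu <- rowMeans(spec$power)
  mu[mu == 0] <- 1
  spec$power <- 100 * (spec$power / mu - 1)
  spec$normalized <- TRUE
  spec
}

#' Average spectrograms over electrodes of interest
#'
#' Element-wise mean over the named channels (default: the 7
#' centro-parietal electrodes where movement-related beta modulation is
#' maximal).
#'
#' @param specs named list of per-channel `spectrogram`s (as returned by
#'   [stft_power()] on a multichannel recording).
#' @param electrodes channel names to average; all must be present.
#' @return a single `spectrogram`.
#' @export
roi_average <- function(specs,
                        electrodes = c("Cz", "CPz", "Pz", "C1", "C3", "C2",
                                       "C4")) {
  missing <- setdiff(electrodes, names(specs))
  if (length(missing))
    stop(sprintf("missing electrode label(s): %s",
                 paste(missing, collapse = ", ")))
  sel <- specs[electrodes]
  out <- sel[[1L]]
  out$power <- Reduce(`+`, lapply(sel, `[[`, "power")) / length(sel)
  attr(out, "electrodes_used") <- electrodes
  out
}

#' Detect beta desynchronization and rebound onsets
#'
#' On a per-bin-normalized ROI spectrogram: the desynchronization onset is
#' the first step at or before movement onset (t = 0) from which the mean
#' beta-band percent change stays below `-threshold` for at least
#' `persistence` consecutive steps; the rebound onset is the first step at
#' or after the holding onset from which it stays above `+threshold`.
#' Events without a qualifying crossing are reported as `NA`.
#'
#' @param spec normalized `spectrogram` spanning 1.5 s around both onsets.
#' @param hold_t holding-onset time (s) on the spectrogram clock.
#' @param beta beta band edges in Hz (default 13-30).
#' @param threshold percent-change threshold (default 10).
#' @param persistence minimum consecutive steps (default 3).
#' @return list with `desync` and `rebound` onset times in seconds
#'   (NA when absent).
#' @export
detect_beta_events <- function(spec, hold_t, beta = c(13, 30),
                               threshold = 10, persistence = 3L) {
  if (!spec$normalized) stop("normalize the spectrogram first")
  bb <- spec$freqs >= beta[1] & spec$freqs <= beta[2]
  if (!any(bb)) stop("no frequency bins inside the beta band")
  series <- colMeans(spec$power[bb, , drop = FALSE])
  first_sustained <- function(idx, cmp) {
    for (i in idx) {
      if (i + persistence - 1L > length(series)) break
      if (all(cmp(series[i:(i + persistence - 1L)]))) return(spec$times[i])
    }
    NA_real_
  }
  pre <- which(spec$times <= 0)
  post <- which(spec$times >= hold_t)
  list(desync = first_sustained(pre, function(v) v < -threshold),
       rebound = first_sustained(post, function(v) v > threshold))
}

#' Most frequent microstate at an event time point
#'
#' Counts, across epochs, the microstate active at the event sample and
#' returns the modal state with the full count table.  Ties are reported
#' with `modal = NA` and `tied` listing the tied states.
#'
#' @param segs list of per-epoch [segmentation()]s.
#' @param event_sample event sample index per epoch (scalar recycled, or a
#'   vector of length = epochs).
#' @param n_states number of states.
#' @return list with `modal`, `counts`, `tied`.
#' @export
microstate_at_event <- function(segs, event_sample, n_states) {
  event_sample <- rep_len(event_sample, length(segs))
  at <- mapply(function(s, i) s$labels[i], segs, event_sample)
  counts <- tabulate(at, nbins = n_states)
  top <- which(counts == max(counts))
  list(modal = if (length(top) == 1L) top else NA_integer_,
       counts = counts,
       tied = if (length(top) > 1L) top else integer(0))
}
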
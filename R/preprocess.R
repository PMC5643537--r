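#' Band-pass filter EEG (1-40 Hz, zero phase)
#'
#' 4th-order Butterworth high-pass and low-pass in cascade, each applied
#' forward-backward (zero net phase); signal length is preserved.  The
#' filters run as second-order sections — a single transfer function of
#' this order is numerically unstable at a 1 Hz cutoff relative to
#' acquisition-level rates.
#'
#' @param rec an EEG [recording] with rate > 80 Hz.
#' @param band filter band edges in Hz.
#' @return the filtered [recording].
#' @export
filter_eeg <- function(rec, band = c(1, 40)) {
  if (rec$modality != "EEG") stop("filter_eeg expects an EEG recording")
  if (rec$rate <= 2 * band[2]) stop("sampling rate too low for the band; resample later in the pipeline")
  secs <- c(butter_sos(4, band[1] / (rec$rate / 2), "high"),
            butter_sos(4, band[2] / (rec$rate / 2), "low"))
  # remove the DC offset first: the high-pass transient of a 1 Hz cutoff
  # decays over seconds and would otherwise leak offset into the output
  rec$data <- t(apply(rec$data, 1L, function(x)
    sos_filtfilt(secs, x - mean(x))))
  rec
}

#' Resample a recording (anti-aliased)
#'
#' Polyphase resampling to `target` Hz with proportional remapping of
#' event sample indices.  Only downsampling is supported (the pipeline
#' filters to 1-40 Hz first).
#'
#' @param rec a [recording].
#' @param target target rate in Hz (<= current rate).
#' @return the resampled [recording].
#' @export
resample_recording <- function(rec, target = 128) {
  if (target > rec$rate) stop("upsampling not supported")
  if (target == rec$rate) return(rec)
  p <- round(target * 1000); q <- round(rec$rate * 1000)
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  d <- g(p, q); pq <- c(p, q) / d
  n_out <- round(ncol(rec$data) * target / rec$rate)
  newdata <- t(apply(rec$data, 1L, function(x)
    signal::resample(x, pq[1L], pq[2L])[seq_len(n_out)]))
  ev <- rec$events
  if (nrow(ev))
    ev$sample <- pmax(1L, pmin(n_out, round(ev$sample * target / rec$rate)))
  recording(newdata, target, labels = rec$labels, modality = rec$modality,
            events = ev)
}

#' Re-reference to the common average
#'
#' Subtracts the per-sample channel mean; idempotent.
#'
#' @param rec a [recording] with at least two channels.
#' @export
rereference_average <- function(rec) {
  if (nrow(rec$data) < 2L) stop("average reference needs >= 2 channels")
  rec$data <- rec$data - rep(colMeans(rec$data), each = nrow(rec$data))
  rec
}

# shared epoching core; span_fn(onset, hold) -> c(first, last) sample
.extract_epochs <- function(rec, span_fn, task = NA_character_) {
  ev <- rec$events
  onsets <- ev$sample[ev$label == "movement_onset"]
  holds <- ev$sample[ev$label == "holding_onset"]
  n_trials <- length(onsets)
  if (n_trials == 0L) stop("no valid trials to epoch")
  epochs <- list(); landmarks <- NULL
  kept <- logical(0); discarded <- data.frame(trial = integer(), reason = character())
  for (i in seq_len(n_trials)) {
    on <- onsets[i]
    # the matching holding onset must precede the next trial's movement
    next_on <- if (i < n_trials) onsets[i + 1L] else Inf
    hd <- holds[holds > on & holds < next_on]
    hd <- if (length(hd)) hd[1L] else NA_integer_
    if (is.na(hd)) {
      kept <- c(kept, FALSE)
      discarded <- rbind(discarded,
                         data.frame(trial = i, reason = "missing event"))
      next
    }
    span <- span_fn(on, hd)
    if (span[1L] < 1L || span[2L] > ncol(rec$data)) {
      kept <- c(kept, FALSE)
      discarded <- rbind(discarded,
                         data.frame(trial = i, reason = "epoch outside recording"))
      next
    }
    kept <- c(kept, TRUE)
    epochs[[length(epochs) + 1L]] <-
      rec$data[, span[1L]:span[2L], drop = FALSE]
    landmarks <- rbind(landmarks,
                       data.frame(onset = on - span[1L] + 1L,
                                  hold = hd - span[1L] + 1L))
  }
  if (length(epochs) == 0L) stop("no valid trials to epoch")
  epoch_set(epochs, rec$rate, task = task, landmarks = landmarks,
            kept = kept, discarded = discarded)
}

#' Extract movement-phase epochs
#'
#' One epoch per trial spanning 2 s before movement onset up to (but not
#' including) the holding onset.
#'
#' @param rec a [recording] whose events contain `movement_onset` and
#'   `holding_onset` per trial (trials missing either are discarded and
#'   logged in the returned set).
#' @param task task label carried into the [epoch_set()].
#' @export
epoch_movement <- function(rec, task = NA_character_) {
  pre <- round(2 * rec$rate)
  .extract_epochs(rec, function(on, hd) c(on - pre, hd - 1L), task)
}

#' Extract holding-phase epochs
#'
#' One epoch per trial spanning the holding onset to 2 s after it.
#' @inheritParams epoch_movement
#' @export
epoch_holding <- function(rec, task = NA_character_) {
  post <- round(2 * rec$rate)
  .extract_epochs(rec, function(on, hd) c(hd, hd + post - 1L), task)
}

#' Discard epochs exceeding an amplitude threshold
#'
#' Stand-in for visual artifact inspection on real data: epochs whose
#' absolute amplitude exceeds `threshold` anywhere are discarded and
#' logged.
#'
#' @param eps an [epoch_set()].
#' @param threshold amplitude bound (same units as the data; default 100).
#' @export
reject_artifacts <- function(eps, threshold = 100) {
  bad <- vapply(eps$epochs, function(e) max(abs(e)) > threshold, TRUE)
  if (all(bad)) stop("all epochs exceed the amplitude threshold")
  eps$discarded <- rbind(eps$discarded,
                         data.frame(trial = which(bad),
                                    reason = "amplitude threshold"))
  eps$epochs <- eps$epochs[!bad]
  eps$landmarks <- eps$landmarks[!bad, , drop = FALSE]
  eps$kept[eps$kept][bad] <- FALSE
  eps
}

#' Equalize epoch lengths by cubic-spline interpolation
#'
#' All epochs are time-interpolated to the rounded mean epoch length using
#' cubic splines; endpoints are preserved exactly (interpolating splines
#' pass through the knots).
#'
#' @param eps an [epoch_set()] with at least one epoch.
#' @export
equalize_epoch_lengths <- function(eps) {
  lens <- vapply(eps$epochs, ncol, 1L)
  if (any(lens < 4L)) stop("epoch shorter than 4 samples: spline undefined")
  m <- round(mean(lens))
  eps$epochs <- lapply(seq_along(eps$epochs), function(i) {
    e <- eps$epochs[[i]]
    if (ncol(e) == m) return(e)
    grid <- seq(1, ncol(e), length.out = m)
    t(apply(e, 1L, function(ch) stats::splinefun(seq_len(ncol(e)), ch)(grid)))
  })
  eps$landmarks$onset <- round((eps$landmarks$onset - 1L) * (m - 1L) /
                                 (lens - 1L)) + 1L
  eps$landmarks$hold <- round((eps$landmarks$hold - 1L) * (m - 1L) /
                                (lens - 1L)) + 1L
  eps
}

#' Average equalized epochs into a single recording
#'
#' Element-wise mean across kept epochs; the landmark attached to the
#' result is the mean onset/hold index.
#'
#' @param eps an [epoch_set()] with equalized lengths.
#' @return a [recording] with attribute `"landmarks"`.
#' @export
average_epochs <- function(eps) {
  if (length(eps$epochs) == 0L) stop("all epochs discarded")
  lens <- vapply(eps$epochs, ncol, 1L)
  if (length(unique(lens)) != 1L) stop("epochs must be equalized first")
  avg <- Reduce(`+`, eps$epochs) / length(eps$epochs)
  out <- recording(avg, eps$rate, modality = "EEG")
  attr(out, "landmarks") <- data.frame(
    onset = round(mean(eps$landmarks$onset)),
    hold = round(mean(eps$landmarks$hold)))
  out
}

#' EMG conditioning to normalized envelopes
#'
#' Linear detrend, 50 Hz high-pass (7th-order Butterworth, zero-phase),
#' rectification, 10 Hz low-pass (7th-order Butterworth, zero-phase),
#' normalization by per-muscle maximum voluntary contraction, and clipping
#' of residual negative filter ringing to zero (the downstream
#' factorization requires nonnegativity).  The high-order filters are
#' applied as cascades of zero-phase biquads for numerical stability at
#' low relative cutoffs.
#'
#' @param rec an EMG [recording].
#' @param mvc per-muscle maximum voluntary contraction (positive scalar or
#'   vector of length = muscles).
#' @return the enveloped [recording] in MVC-fraction units.
#' @export
process_emg <- function(rec, mvc) {
  if (rec$modality != "EMG") stop("process_emg expects an EMG recording")
  mvc <- rep_len(mvc, nrow(rec$data))
  if (any(mvc <= 0)) stop("MVC entries must be positive")
  hp <- butter_sos(7, 50 / (rec$rate / 2), "high")
  lp <- butter_sos(7, 10 / (rec$rate / 2), "low")
  n <- ncol(rec$data)
  tt <- seq_len(n)
  env <- t(apply(rec$data, 1L, function(x) {
    x <- stats::lm.fit(cbind(1, tt), x)$residuals           # linear detrend
    x <- sos_filtfilt(hp, x)
    x <- abs(x)
    sos_filtfilt(lp, x)
  }))
  env <- env / mvc
  env[env < 0] <- 0
  recording(env, rec$rate, labels = rec$labels, modality = "EMG",
            events = rec$events)
}
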
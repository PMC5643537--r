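#' Multichannel recording container
#'
#' A lightweight container for a continuous multichannel biosignal:
#' a channels x samples numeric matrix plus sampling rate, channel labels,
#' a modality tag and an events table.
#'
#' @param data numeric matrix, channels x samples.
#' @param rate sampling rate in Hz (> 0).
#' @param labels character vector of channel names (length = nrow(data)).
#' @param modality `"EEG"` or `"EMG"`.
#' @param events data.frame with columns `sample` (1-based index) and
#'   `label`, or `NULL`.
#' @return an object of class `recording`.
#' @export
recording <- function(data, rate, labels = NULL, modality = c("EEG", "EMG"),
                      events = NULL) {
  modality <- match.arg(modality)
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("recording data must be numeric")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a positive scalar (Hz)")
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  if (length(labels) != nrow(data))
    stop("labels length must equal channel count")
  if (is.null(events)) events <- data.frame(sample = integer(), label = character())
  if (!all(c("sample", "label") %in% names(events)))
    stop("events must have columns 'sample' and 'label'")
  if (nrow(events) && (any(events$sample < 1L) || any(events$sample > ncol(data))))
    stop("event sample indices must lie within [1, samples]")
  structure(list(data = data, rate = rate, labels = labels,
                 modality = modality, events = events),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s: %d channels x %d samples @ %g Hz, %d events\n",
              x$modality, nrow(x$data), ncol(x$data), x$rate, nrow(x$events)))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec a [recording].
#' @export
duration <- function(rec) ncol(rec$data) / rec$rate

#' Set of epochs extracted from a recording
#'
#' @param epochs list of channels x samples numeric matrices (lengths may
#'   differ before [equalize_epoch_lengths()]).
#' @param rate sampling rate in Hz.
#' @param task task label.
#' @param landmarks data.frame with per-epoch `onset` and `hold` sample
#'   indices (relative to the epoch start; NA if outside the epoch).
#' @param kept logical vector: which of the original trials were retained.
#' @param discarded data.frame log of discarded trials with a `reason` column.
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(epochs, rate, task = NA_character_, landmarks = NULL,
                      kept = NULL, discarded = NULL) {
  stopifnot(is.list(epochs))
  if (is.null(kept)) kept <- rep(TRUE, length(epochs))
  if (is.null(landmarks))
    landmarks <- data.frame(onset = rep(NA_integer_, length(epochs)),
                            hold = rep(NA_integer_, length(epochs)))
  if (is.null(discarded))
    discarded <- data.frame(trial = integer(), reason = character())
  structure(list(epochs = epochs, rate = rate, task = task,
                 landmarks = landmarks, kept = kept, discarded = discarded),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  lens <- vapply(x$epochs, ncol, 1L)
  cat(sprintf("<epoch_set> task=%s: %d epochs @ %g Hz, lengths %s\n",
              x$task, length(x$epochs), x$rate,
              if (length(lens)) paste(range(lens), collapse = "-") else "-"))
  invisible(x)
}
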
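# Minimal EDF (16-bit) / BDF (24-bit) writer and reader.
# Covers the subset of the format this package emits: one data record
# holding the whole signal, identical rate across channels, no
# annotations (events travel in a sidecar table; see write_dataset()).

pad <- function(s, n) {
  s <- substr(as.character(s), 1L, n)
  paste0(s, strrep(" ", n - nchar(s)))
}

# per-channel symmetric physical amplitude, chosen so that its 8-character
# header representation parses back to a value >= the data amplitude (the
# header string, not the raw amplitude, defines the gain on read)
fmt_amp <- function(M) {
  if (!is.finite(M) || M <= 0) M <- 1
  for (d in 6:2) {
    s <- formatC(M * (1 + 10^(-d + 1)), digits = d, format = "g", width = 0)
    v <- suppressWarnings(as.numeric(s))
    # <= 7 chars so the negated form also fits the 8-character field
    if (nchar(s) <= 7L && is.finite(v) && v >= M) return(list(s = s, v = v))
  }
  stop("channel amplitude not representable in an EDF header field")
}

#' Write a recording as EDF or BDF
#'
#' EDF stores samples as 16-bit integers, BDF as 24-bit; each channel is
#' scaled to its own physical min/max, so a round-trip is exact up to the
#' corresponding quantization step.
#'
#' @param rec a [recording].
#' @param path output file path.
#' @param format `"edf"` or `"bdf"`.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, format = c("edf", "bdf")) {
  format <- match.arg(format)
  nch <- nrow(rec$data); ns <- ncol(rec$data)
  dig_max <- if (format == "edf") 32767 else 8388607
  con <- file(path, "wb")
  on.exit(close(con))
  if (format == "edf") {
    writeChar(pad("0", 8L), con, eos = NULL)
  } else {
    writeBin(as.raw(255L), con)
    writeChar(pad("BIOSEMI", 7L), con, eos = NULL)
  }
  writeChar(pad("X", 80L), con, eos = NULL)                   # patient
  writeChar(pad(rec$modality, 80L), con, eos = NULL)          # recording
  writeChar(pad("01.01.00", 8L), con, eos = NULL)
  writeChar(pad("00.00.00", 8L), con, eos = NULL)
  writeChar(pad(256L * (1L + nch), 8L), con, eos = NULL)
  writeChar(pad(if (format == "edf") "" else "24BIT", 44L), con, eos = NULL)
  writeChar(pad("1", 8L), con, eos = NULL)                    # 1 record
  writeChar(pad(format(ns / rec$rate, digits = 8), 8L), con, eos = NULL)
  writeChar(pad(nch, 4L), con, eos = NULL)
  for (lab in rec$labels) writeChar(pad(lab, 16L), con, eos = NULL)
  for (i in seq_len(nch)) writeChar(pad("", 80L), con, eos = NULL)
  for (i in seq_len(nch)) writeChar(pad("uV", 8L), con, eos = NULL)
  amp <- lapply(seq_len(nch), function(i) fmt_amp(max(abs(rec$data[i, ]))))
  for (i in seq_len(nch)) writeChar(pad(paste0("-", amp[[i]]$s), 8L), con, eos = NULL)
  for (i in seq_len(nch)) writeChar(pad(amp[[i]]$s, 8L), con, eos = NULL)
  for (i in seq_len(nch)) writeChar(pad(-dig_max, 8L), con, eos = NULL)
  for (i in seq_len(nch)) writeChar(pad(dig_max, 8L), con, eos = NULL)
  for (i in seq_len(nch)) writeChar(pad("", 80L), con, eos = NULL)
  for (i in seq_len(nch)) writeChar(pad(ns, 8L), con, eos = NULL)
  for (i in seq_len(nch)) writeChar(pad("", 32L), con, eos = NULL)
  for (i in seq_len(nch)) {
    dig <- round(rec$data[i, ] / amp[[i]]$v * dig_max)
    dig <- pmax(pmin(dig, dig_max), -dig_max)
    if (format == "edf") {
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    } else {
      u <- as.integer(dig)
      u[u < 0] <- u[u < 0] + 16777216L
      bytes <- rbind(u %% 256L, (u %/% 256L) %% 256L, u %/% 65536L)
      writeBin(as.raw(bytes), con)
    }
  }
  invisible(path)
}

#' Read an EDF or BDF file
#'
#' Reads files written by [write_edf()] and standard single-rate EDF/BDF
#' files without annotation channels.
#'
#' @param path file path.
#' @param modality modality tag for the returned [recording].
#' @return a [recording] (events empty; see [read_dataset()] for the
#'   sidecar events table).
#' @export
read_edf <- function(path, modality = "EEG") {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8L)
  format <- if (magic[1L] == as.raw(255L)) "bdf" else "edf"
  rd_str <- function(n) {
    trimws(rawToChar(readBin(con, "raw", n)))
  }
  rd_str(80L); rd_str(80L); rd_str(8L); rd_str(8L)
  rd_str(8L)                                  # header bytes
  rd_str(44L)
  n_rec <- as.integer(rd_str(8L))
  rec_dur <- as.numeric(rd_str(8L))
  nch <- as.integer(rd_str(4L))
  labels <- vapply(seq_len(nch), function(i) rd_str(16L), "")
  for (i in seq_len(nch)) rd_str(80L)
  for (i in seq_len(nch)) rd_str(8L)
  pmin_ <- vapply(seq_len(nch), function(i) as.numeric(rd_str(8L)), 0)
  pmax_ <- vapply(seq_len(nch), function(i) as.numeric(rd_str(8L)), 0)
  dmin <- vapply(seq_len(nch), function(i) as.numeric(rd_str(8L)), 0)
  dmax <- vapply(seq_len(nch), function(i) as.numeric(rd_str(8L)), 0)
  for (i in seq_len(nch)) rd_str(80L)
  spr <- vapply(seq_len(nch), function(i) as.integer(rd_str(8L)), 0L)
  for (i in seq_len(nch)) rd_str(32L)
  if (length(unique(spr)) != 1L)
    stop("mixed per-channel rates are not supported")
  data <- matrix(0, nch, spr[1L] * n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(nch)) {
      if (format == "edf") {
        dig <- readBin(con, "integer", spr[i], size = 2L, endian = "little")
      } else {
        bytes <- as.integer(readBin(con, "raw", 3L * spr[i]))
        m <- matrix(bytes, nrow = 3L)
        dig <- m[1L, ] + 256L * m[2L, ] + 65536L * m[3L, ]
        dig[dig >= 8388608L] <- dig[dig >= 8388608L] - 16777216L
      }
      phys <- pmin_[i] + (dig - dmin[i]) / (dmax[i] - dmin[i]) *
        (pmax_[i] - pmin_[i])
      data[i, (r - 1L) * spr[i] + seq_len(spr[i])] <- phys
    }
  }
  recording(data, spr[1L] / rec_dur, labels = labels, modality = modality)
}
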
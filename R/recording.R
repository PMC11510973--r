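#' Multichannel recording
#'
#' Container for a multichannel time series: a channels x time sample
#' matrix with a sampling rate, ordered channel names, and a modality tag.
#'
#' @param samples Numeric matrix, channels x time.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_names Character vector, one name per row of `samples`.
#' @param modality One of `"EEG"`, `"HBO"`, `"HBR"`, `"COE"`.
#' @param t0 Start time in seconds (default 0).
#' @return An object of class `recording`.
#' @export
recording <- function(samples, fs, channel_names,
                      modality = c("EEG", "HBO", "HBR", "COE"), t0 = 0) {
  modality <- match.arg(modality)
  samples <- as.matrix(samples)
  if (length(channel_names) != nrow(samples))
    stop("channel_names length (", length(channel_names),
         ") must match rows of samples (", nrow(samples), ")")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("fs must be a positive scalar")
  if (anyNA(samples)) stop("samples contain NA")
  rownames(samples) <- channel_names
  structure(
    list(samples = samples, fs = fs, channel_names = as.character(channel_names),
         modality = modality, t0 = t0),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$modality, nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs))
  cat("channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec A `recording`.
#' @return Scalar seconds.
#' @export
rec_duration <- function(rec) ncol(rec$samples) / rec$fs

#' Write a recording to CSV
#'
#' First column is time in seconds, remaining columns are channels (one
#' column per channel, named by the header).
#'
#' @param rec A `recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  tt <- rec$t0 + (seq_len(ncol(rec$samples)) - 1) / rec$fs
  df <- data.frame(time = tt, t(rec$samples), check.names = FALSE)
  names(df) <- c("time", rec$channel_names)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a recording from CSV or EDF
#'
#' CSV dialect: first column is time in seconds and must be uniformly
#' spaced (tolerance 1e-6 s); remaining columns are channels. EDF dialect:
#' 16-bit continuous EDF as written by [write_recording_edf()]. For
#' full-montage EEG files the channels are reordered to the canonical
#' montage order of [eeg_montage()]; unknown channel names are an error.
#'
#' @param path File path.
#' @param modality Modality tag for the returned recording.
#' @param dialect `"csv"` or `"edf"`.
#' @return A `recording`.
#' @export
read_recording <- function(path, modality = "EEG", dialect = c("csv", "edf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  rec <- if (dialect == "csv") read_recording_csv_impl(path, modality)
         else read_recording_edf_impl(path, modality)
  canonicalize_channels(rec)
}

read_recording_csv_impl <- function(path, modality) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2) stop("CSV must have a time column plus >= 1 channel: ", path)
  if (anyNA(df)) {
    bad <- which(apply(df, 1, anyNA))[1]
    stop("ragged or missing values in ", path, " at data line ", bad)
  }
  tt <- df[[1]]
  dt <- diff(tt)
  if (length(dt) < 1) stop("need at least 2 samples: ", path)
  if (max(abs(dt - dt[1])) > 1e-6) {
    bad <- which(abs(dt - dt[1]) > 1e-6)[1] + 1
    stop("non-uniform time grid in ", path, " at data line ", bad)
  }
  fs <- 1 / mean(dt)
  recording(t(as.matrix(df[, -1, drop = FALSE])), fs = fs,
            channel_names = names(df)[-1], modality = modality, t0 = tt[1])
}

canonicalize_channels <- function(rec) {
  if (rec$modality == "EEG" && setequal(rec$channel_names, eeg_montage())) {
    ord <- match(eeg_montage(), rec$channel_names)
    rec$samples <- rec$samples[ord, , drop = FALSE]
    rec$channel_names <- eeg_montage()
  } else if (rec$modality == "EEG" &&
             length(rec$channel_names) == length(eeg_montage())) {
    unknown <- setdiff(rec$channel_names, eeg_montage())
    stop("unknown EEG channel(s): ", paste(unknown, collapse = ", "))
  }
  rec
}

# ---- minimal EDF (European Data Format) support -------------------------
# Continuous 16-bit EDF with one data record per second. Only what the
# pipeline needs: no annotations, no discontinuities. Requires integer
# sampling rates (128 Hz EEG, 10 Hz fNIRS both qualify).

edf_pad <- function(x, width) formatC(as.character(x), width = width, flag = "-")

#' Write a recording as 16-bit EDF
#'
#' Minimal continuous EDF writer (1-second data records, little-endian
#' int16 with per-channel physical scaling). Quantization limits
#' round-trip precision to about 1/65000 of the channel range.
#'
#' @param rec A `recording` with integer `fs` and whole-second duration.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording_edf <- function(rec, path) {
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires integer fs")
  fs <- round(fs)
  ns <- nrow(rec$samples)
  n <- ncol(rec$samples)
  n_rec <- floor(n / fs)
  if (n_rec * fs != n) stop("EDF writer requires whole-second duration")
  pmin_ <- apply(rec$samples, 1, min)
  pmax_ <- apply(rec$samples, 1, max)
  span <- pmax_ - pmin_
  pmin_[span == 0] <- pmin_[span == 0] - 1
  pmax_[span == 0] <- pmax_[span == 0] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(paste0(edf_pad(s, w), collapse = ""), con,
                                 nchars = w * length(s), eos = NULL)
  wr("0", 8)                                   # version
  wr(edf_pad("synthetic", 80), 80)             # patient id
  wr(edf_pad(rec$modality, 80), 80)            # recording id
  wr("01.01.00", 8); wr("00.00.00", 8)         # date, time
  wr(as.character(256 + 256 * ns), 8)          # header bytes
  wr(edf_pad("", 44), 44)                      # reserved
  wr(as.character(n_rec), 8)                   # number of records
  wr("1", 8)                                   # record duration (s)
  wr(as.character(ns), 4)                      # number of signals
  wr(substr(edf_pad(rec$channel_names, 16), 1, 16), 16)
  wr(rep(edf_pad("", 80), ns), 80)             # transducer
  wr(rep(edf_pad("uV", 8), ns), 8)             # physical dimension
  wr(substr(formatC(pmin_, format = "g", width = 8), 1, 8), 8)
  wr(substr(formatC(pmax_, format = "g", width = 8), 1, 8), 8)
  wr(rep(as.character(dmin), ns), 8)
  wr(rep(as.character(dmax), ns), 8)
  wr(rep(edf_pad("", 80), ns), 80)             # prefiltering
  wr(rep(as.character(fs), ns), 8)             # samples per record
  wr(rep(edf_pad("", 32), ns), 32)             # reserved
  # physical values re-read from the header strings so that the reader's
  # scaling reproduces exactly what we quantized against
  pmin_h <- as.numeric(substr(formatC(pmin_, format = "g", width = 8), 1, 8))
  pmax_h <- as.numeric(substr(formatC(pmax_, format = "g", width = 8), 1, 8))
  gain <- (pmax_h - pmin_h) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- round((rec$samples[ch, idx] - pmin_h[ch]) / gain[ch] + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_recording_edf_impl <- function(path, modality) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  out <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[ch], size = 2,
                     endian = "little", signed = TRUE)
      out[ch, ((r - 1) * spr[ch] + 1):(r * spr[ch])] <-
        pmin_[ch] + (dig - dmin[ch]) * gain[ch]
    }
  }
  recording(out, fs = spr[1] / dur, channel_names = labels,
            modality = modality)
}
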
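#' Write a recording to disk
#'
#' Serialises an `mrcp_recording` into a directory. Two formats:
#' * `"delimited"`: `eeg.csv` (header row = channel names, one column per
#'   channel, time implicit from the sampling rate), `force.csv`,
#'   `events.csv` (`cue_time_s`, `task`, `true_onset_s`) and `meta.csv`
#'   (key/value: rates, group). Comma-separated, UTF-8, `.` decimal.
#' * `"edf"`: `eeg.edf` (European Data Format, 16-bit, 1 s data records)
#'   plus the same `force.csv`, `events.csv` and `meta.csv` sidecars. EDF
#'   requires a whole number of records, so the EEG is truncated to a whole
#'   number of seconds, and quantisation limits round-trip precision to
#'   about `range/2^16` per channel.
#'
#' @param recording an `mrcp_recording`.
#' @param path output directory (created if needed).
#' @param format `"delimited"` or `"edf"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, format = c("delimited", "edf")) {
  format <- match.arg(format)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (format == "delimited") {
    data.table::fwrite(as.data.frame(recording$eeg), file.path(path, "eeg.csv"))
  } else {
    write_edf(recording$eeg, recording$fs_eeg, file.path(path, "eeg.edf"))
  }
  data.table::fwrite(data.frame(force = recording$force),
                     file.path(path, "force.csv"))
  data.table::fwrite(data.frame(cue_time_s = recording$cue_times,
                                task = recording$task_labels,
                                true_onset_s = recording$true_onsets),
                     file.path(path, "events.csv"))
  data.table::fwrite(data.frame(key = c("fs_eeg", "fs_force", "group"),
                                value = c(recording$fs_eeg,
                                          recording$fs_force,
                                          recording$group)),
                     file.path(path, "meta.csv"))
  invisible(path)
}

#' Read a recording from disk
#'
#' Counterpart of [write_recording()]. Channels are matched by name,
#' case-insensitively; extra channels are ignored with a message; a missing
#' required channel raises an error naming it. The EEG rate is taken from
#' the EDF header when reading EDF, otherwise from `meta.csv`.
#'
#' @param path directory written by [write_recording()].
#' @param format `"auto"` (detect from files present), `"delimited"` or
#'   `"edf"`.
#' @return an `mrcp_recording`.
#' @export
read_recording <- function(path, format = c("auto", "delimited", "edf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (file.exists(file.path(path, "eeg.edf"))) "edf" else "delimited"
  }
  meta <- data.table::fread(file.path(path, "meta.csv"),
                            colClasses = list(character = "value"))
  mval <- function(k) meta$value[match(k, meta$key)]
  if (format == "delimited") {
    eeg <- as.matrix(data.table::fread(file.path(path, "eeg.csv")))
    fs_eeg <- as.numeric(mval("fs_eeg"))
  } else {
    e <- read_edf(file.path(path, "eeg.edf"))
    eeg <- e$signals
    fs_eeg <- e$fs
  }
  idx <- match(tolower(EEG_CHANNELS), tolower(colnames(eeg)))
  required <- setdiff(EEG_CHANNELS, "FP1") # FP1 is EOG, optional on read
  miss <- EEG_CHANNELS[is.na(idx)]
  if (any(required %in% miss)) {
    stop("missing required channel(s): ",
         paste(intersect(required, miss), collapse = ", "))
  }
  extras <- setdiff(colnames(eeg), colnames(eeg)[idx[!is.na(idx)]])
  if (length(extras)) {
    message("ignoring extra channel(s): ", paste(extras, collapse = ", "))
  }
  present <- EEG_CHANNELS[!is.na(idx)]
  eeg <- eeg[, idx[!is.na(idx)], drop = FALSE]
  colnames(eeg) <- present
  if (anyNA(idx)) { # absent optional channels filled with zeros
    full <- matrix(0, nrow(eeg), length(EEG_CHANNELS),
                   dimnames = list(NULL, EEG_CHANNELS))
    full[, present] <- eeg
    eeg <- full
  }
  events <- data.table::fread(file.path(path, "events.csv"))
  force <- data.table::fread(file.path(path, "force.csv"))$force
  structure(list(eeg = eeg, fs_eeg = fs_eeg, force = force,
                 fs_force = as.numeric(mval("fs_force")),
                 cue_times = events$cue_time_s,
                 task_labels = as.character(events$task),
                 true_onsets = events$true_onset_s,
                 group = mval("group")),
            class = "mrcp_recording")
}

# --- Minimal EDF (European Data Format) support -----------------------------
# EDF is a fixed-layout ASCII-header format with 16-bit little-endian samples
# arranged in fixed-duration data records. Only continuous equal-rate signal
# storage is needed here (no annotations). One-second records, one signal per
# EEG channel.

edf_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width) # left-justified, space-padded
}

edf_num <- function(x, width) {
  s <- formatC(signif(x, width - 2), format = "g", digits = width - 2)
  if (nchar(s) > width) s <- substr(s, 1, width)
  edf_field(s, width)
}

write_edf <- function(signals, fs, file) {
  ns <- ncol(signals)
  n_rec <- floor(nrow(signals) / fs)
  if (n_rec < 1) stop("recording shorter than one EDF data record (1 s)")
  signals <- signals[seq_len(n_rec * fs), , drop = FALSE]
  pmin_ <- apply(signals, 2, min)
  pmax_ <- apply(signals, 2, max)
  flat <- pmax_ - pmin_ == 0
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  # the header stores the physical range as short ASCII numbers; widen the
  # true range outward to what the header will actually say, so scaling on
  # write matches what a reader reconstructs
  pmin_ <- pmin(pmin_, as.numeric(vapply(pmin_, edf_num, "", width = 8))) - 1e-9
  pmax_ <- pmax(pmax_, as.numeric(vapply(pmax_, edf_num, "", width = 8))) + 1e-9
  pmin_ <- as.numeric(vapply(pmin_, edf_num, "", width = 8))
  pmax_ <- as.numeric(vapply(pmax_, edf_num, "", width = 8))
  dmin <- -32768; dmax <- 32767

  con <- file(file, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8),
    edf_field("X X X X", 80),
    edf_field("Startdate 01-JAN-2000 X X X", 80),
    edf_field("01.01.00", 8), edf_field("00.00.00", 8),
    edf_field(256 * (ns + 1), 8),
    edf_field("", 44),
    edf_field(n_rec, 8),
    edf_field("1", 8),
    edf_field(ns, 4))
  sig_hdr <- paste0(
    paste(vapply(colnames(signals), edf_field, "", width = 16), collapse = ""),
    paste(rep(edf_field("", 80), ns), collapse = ""),
    paste(rep(edf_field("uV", 8), ns), collapse = ""),
    paste(vapply(pmin_, edf_num, "", width = 8), collapse = ""),
    paste(vapply(pmax_, edf_num, "", width = 8), collapse = ""),
    paste(rep(edf_field(dmin, 8), ns), collapse = ""),
    paste(rep(edf_field(dmax, 8), ns), collapse = ""),
    paste(rep(edf_field("", 80), ns), collapse = ""),
    paste(rep(edf_field(fs, 8), ns), collapse = ""),
    paste(rep(edf_field("", 32), ns), collapse = ""))
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL)
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1) * fs + 1):(r * fs)
    for (j in seq_len(ns)) {
      dig <- round((signals[rows, j] - pmin_[j]) /
                     (pmax_[j] - pmin_[j]) * (dmax - dmin) + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(file)
}

read_edf <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8) # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80) # transducer
  for (i in seq_len(ns)) rd(8)  # physical dimension
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80) # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  sig <- matrix(0, n_rec * spr[1], ns, dimnames = list(NULL, labels))
  for (r in seq_len(n_rec)) {
    for (j in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[j], size = 2, endian = "little",
                     signed = TRUE)
      rows <- ((r - 1) * spr[j] + 1):(r * spr[j])
      sig[rows, j] <- (dig - dmin[j]) / (dmax[j] - dmin[j]) *
        (pmax_[j] - pmin_[j]) + pmin_[j]
    }
  }
  list(signals = sig, fs = spr[1] / rec_dur)
}
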
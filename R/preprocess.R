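#' @name preprocess
#' @title Surrogate-channel preprocessing
#' @description
#' Nine scalp channels (FP1 excluded as EOG) are reduced to a single
#' surrogate channel by a large Laplacian spatial filter, then filtered
#' temporally along two paths: a 0.05-10 Hz band-pass feeding the temporal
#' features and the MRCP template, and a 0.05 Hz high-pass feeding the
#' spectral features. Both filters are 2nd-order Butterworth designs applied
#' forward and reverse (zero net phase).
NULL

# Zero-phase filtering: odd (point-symmetric) reflection padding at both
# ends, filter forward, reverse, filter again, reverse, unpad. The odd
# reflection continues the signal without a step, which matters for the
# 0.05 Hz corners whose transients are seconds long.
zero_phase_filter <- function(x, filt, pad_len) {
  n <- length(x)
  if (n < 8) stop("series too short for stable forward-reverse filtering")
  p <- min(n - 1, pad_len)
  xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  y <- as.numeric(signal::filter(filt, xp))
  y <- rev(as.numeric(signal::filter(filt, rev(y))))
  y[(p + 1):(p + n)]
}

# Pad with 3x the effective impulse length of the slowest corner
# (~ fs / f_low samples).
filter_pad_length <- function(fs, f_low) ceiling(3 * fs / f_low)

#' Band-pass filter for the MRCP temporal path
#'
#' 2nd-order Butterworth band-pass with 0.05 and 10 Hz corners, applied in
#' the forward and reverse direction so the net phase is zero. Output length
#' equals input length.
#'
#' @param x numeric series in microvolts.
#' @param fs sampling rate in Hz; must exceed twice the upper corner.
#' @param low,high corner frequencies in Hz.
#' @return filtered series, same length as `x`.
#' @export
bandpass_mrcp <- function(x, fs, low = 0.05, high = 10) {
  if (fs <= 2 * high) {
    stop("fs must exceed ", 2 * high, " Hz for a ", high, " Hz corner")
  }
  flt <- signal::butter(2, c(low, high) / (fs / 2), type = "pass")
  zero_phase_filter(x, flt, filter_pad_length(fs, low))
}

#' High-pass filter for the spectral path
#'
#' 2nd-order Butterworth high-pass with a 0.05 Hz cut-off, forward-reverse.
#' Removes DC and infra-slow drift while preserving all bands up to Nyquist.
#'
#' @inheritParams bandpass_mrcp
#' @param cutoff corner frequency in Hz.
#' @return filtered series, same length as `x`.
#' @export
highpass_spectral <- function(x, fs, cutoff = 0.05) {
  flt <- signal::butter(2, cutoff / (fs / 2), type = "high")
  zero_phase_filter(x, flt, filter_pad_length(fs, cutoff))
}

#' Large Laplacian surrogate channel
#'
#' Samplewise `Cz - mean(F3, Fz, F4, C3, C4, P3, Pz, P4)`. With nine scalp
#' channels the eight non-Cz channels form the surrounding ring, each with
#' weight -1/8; the weights sum to zero, so any common-mode component
#' (e.g. a reference shift) cancels exactly. FP1 (EOG) is ignored.
#'
#' @param eeg numeric matrix, samples x channels, with channel names as
#'   column names (matched case-insensitively).
#' @param channel_names optional channel names overriding `colnames(eeg)`.
#' @return numeric vector: the surrogate channel in microvolts.
#' @export
laplacian_surrogate <- function(eeg, channel_names = colnames(eeg)) {
  if (is.null(channel_names)) stop("eeg must have channel names")
  idx <- match(tolower(LAPLACIAN_CHANNELS), tolower(channel_names))
  if (anyNA(idx)) {
    stop("missing required channel(s): ",
         paste(LAPLACIAN_CHANNELS[is.na(idx)], collapse = ", "))
  }
  names(idx) <- LAPLACIAN_CHANNELS
  ring <- idx[setdiff(LAPLACIAN_CHANNELS, "Cz")]
  eeg[, idx[["Cz"]]] - rowMeans(eeg[, ring, drop = FALSE])
}

#' Preprocess a recording into the two surrogate paths
#'
#' Applies the Laplacian spatial filter first and then the two temporal
#' filters to the single surrogate series (equivalent, by linearity, to
#' filtering each channel before combining, but nine times cheaper).
#'
#' @param recording an `mrcp_recording` (or any list with `eeg` and `fs_eeg`).
#' @return An object of class `surrogate_pair`: list with `temporal`
#'   (0.05-10 Hz band-passed surrogate), `spectral` (0.05 Hz high-passed
#'   surrogate) and `fs`.
#' @export
surrogate_channels <- function(recording) {
  s <- laplacian_surrogate(recording$eeg)
  fs <- recording$fs_eeg
  structure(list(temporal = bandpass_mrcp(s, fs),
                 spectral = highpass_spectral(s, fs),
                 fs = fs),
            class = "surrogate_pair")
}
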
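#' Detect movement onset from the force trace
#'
#' The onset is the first sample at or after the cue such that every sample
#' in the following 200 ms window (advanced one sample at a time) strictly
#' exceeds the baseline, where the baseline is the mean force over 2-4 s
#' before the cue. An optional margin of `margin_sd` baseline standard
#' deviations can be added to the baseline (default 0: the literal rule).
#'
#' @param force numeric force series (fraction of MVC).
#' @param fs force sampling rate in Hz.
#' @param cue_time cue (task-onset) time in seconds on the recording clock;
#'   the trace must cover `cue_time - 4 s` to `cue_time + search_window`.
#' @param search_window seconds after the cue within which the onset must
#'   start (default 5).
#' @param hold length in seconds of the above-baseline window (default 0.2).
#' @param margin_sd multiple of the baseline standard deviation added to the
#'   baseline before comparison (default 0).
#' @return onset time in seconds, or `NA_real_` if no qualifying window
#'   exists (the trial should then be dropped).
#' @export
detect_force_onset <- function(force, fs, cue_time, search_window = 5,
                               hold = 0.2, margin_sd = 0) {
  b0 <- round((cue_time - 4) * fs)
  b1 <- round((cue_time - 2) * fs)
  if (b0 < 0 || b1 > length(force)) {
    stop("force trace does not cover the 2-4 s pre-cue baseline window")
  }
  base <- force[(b0 + 1):b1] # half-open [cue-4, cue-2), 0-based indices
  thr <- mean(base) + margin_sd * stats::sd(base)

  w <- round(hold * fs)
  s0 <- round(cue_time * fs) # first candidate window start (0-based)
  last_start <- min(length(force) - w, round((cue_time + search_window) * fs))
  if (last_start < s0) return(NA_real_)
  v <- force[(s0 + 1):(last_start + w)]
  ok <- v > thr
  cs <- cumsum(ok)
  wins <- cs[w:length(cs)] - c(0, cs[seq_len(length(cs) - w)])
  j <- which(wins == w)[1] # first window with all `w` samples above baseline
  if (is.na(j)) return(NA_real_)
  (s0 + j - 1) / fs
}

#' Resolve per-trial onsets for a recording
#'
#' For real and attempted movements the onset is detected from the force
#' trace per trial. For imaginary movements no force is produced: the
#' cue-defined task onset is used directly, and a guard verifies that the
#' force trace indeed shows no movement (maximum force minus baseline below
#' `force_guard_threshold`), flagging violating trials.
#'
#' @param recording an `mrcp_recording`.
#' @param group subject group; defaults to the recording's own tag.
#' @param force_guard_threshold fraction of MVC above baseline that flags an
#'   imagery trial as actually moved (default 0.05).
#' @param ... passed to [detect_force_onset()].
#' @return data.frame with one row per trial: `trial`, `task`, `cue_time`,
#'   `onset` (NA when not found), `flagged` (imagery guard violations).
#' @export
resolve_onsets <- function(recording, group = recording$group,
                           force_guard_threshold = 0.05, ...) {
  stopifnot(group %in% c("real", "imaginary", "attempted"))
  n <- length(recording$cue_times)
  out <- data.frame(trial = seq_len(n), task = recording$task_labels,
                    cue_time = recording$cue_times, onset = NA_real_,
                    flagged = FALSE, stringsAsFactors = FALSE)
  fs <- recording$fs_force
  for (k in seq_len(n)) {
    cue <- recording$cue_times[k]
    if (group == "imaginary") {
      out$onset[k] <- cue
      b0 <- round((cue - 4) * fs); b1 <- round((cue - 2) * fs)
      base <- mean(recording$force[(b0 + 1):b1])
      seg <- recording$force[(round(cue * fs) + 1):
                               min(length(recording$force),
                                   round((cue + 5) * fs))]
      out$flagged[k] <- max(seg) - base > force_guard_threshold
    } else {
      out$onset[k] <- detect_force_onset(recording$force, fs, cue, ...)
    }
  }
  out
}

#' Extract signal and noise epochs from a surrogate path
#'
#' Per trial, one 2 s movement epoch covering `[onset - 2 s, onset)` and one
#' 2 s noise epoch covering `[onset - 5 s, onset - 3 s)`, both cut from the
#' requested preprocessing path. Windows are half-open with 0-based start
#' index `round(t * fs)`, so a 2 s epoch at 500 Hz is exactly 1000 samples.
#' Trials whose windows fall outside the recording (or whose onset is NA)
#' are dropped and reported in the `dropped` component.
#'
#' @param surrogate a `surrogate_pair` from [surrogate_channels()].
#' @param onsets numeric vector of per-trial onset times in seconds.
#' @param tasks character vector of per-trial task ids (same length).
#' @param path `"temporal"` or `"spectral"`.
#' @return An object of class `epoch_set`: list with `samples` (epochs x
#'   samples matrix), `meta` (data.frame: `label` in movement/noise, `task`,
#'   `t0` epoch start time, `trial`), `fs`, `path`, and `dropped`
#'   (data.frame of dropped trials with reasons).
#' @export
extract_epochs <- function(surrogate, onsets, tasks,
                           path = c("temporal", "spectral")) {
  path <- match.arg(path)
  stopifnot(length(onsets) == length(tasks))
  x <- surrogate[[path]]
  fs <- surrogate$fs
  len <- round(2 * fs)
  sig <- list(); noi <- list()
  meta_sig <- list(); meta_noi <- list()
  dropped <- data.frame(trial = integer(), reason = character())
  for (k in seq_along(onsets)) {
    on <- onsets[k]
    if (is.na(on)) {
      dropped <- rbind(dropped, data.frame(trial = k, reason = "onset not found"))
      next
    }
    i_sig <- round((on - 2) * fs) # 0-based start indices
    i_noi <- round((on - 5) * fs)
    if (i_noi < 0 || i_sig + len > length(x)) {
      dropped <- rbind(dropped,
                       data.frame(trial = k, reason = "window out of range"))
      next
    }
    sig[[length(sig) + 1]] <- x[(i_sig + 1):(i_sig + len)]
    noi[[length(noi) + 1]] <- x[(i_noi + 1):(i_noi + len)]
    meta_sig[[length(meta_sig) + 1]] <-
      data.frame(label = "movement", task = tasks[k], t0 = i_sig / fs,
                 trial = k, stringsAsFactors = FALSE)
    meta_noi[[length(meta_noi) + 1]] <-
      data.frame(label = "noise", task = tasks[k], t0 = i_noi / fs,
                 trial = k, stringsAsFactors = FALSE)
  }
  samples <- do.call(rbind, c(sig, noi))
  if (is.null(samples)) samples <- matrix(numeric(), 0, len)
  meta <- do.call(rbind, c(meta_sig, meta_noi))
  if (is.null(meta)) {
    meta <- data.frame(label = character(), task = character(),
                       t0 = numeric(), trial = integer())
  }
  structure(list(samples = samples, meta = meta, fs = fs, path = path,
                 dropped = dropped),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("<epoch_set>", nrow(x$samples), "epochs x", ncol(x$samples),
      "samples @", x$fs, "Hz,", x$path, "path\n")
  tab <- table(x$meta$label)
  cat("  ", paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
  if (nrow(x$dropped)) cat("  dropped trials:", nrow(x$dropped), "\n")
  invisible(x)
}

#' Epochs of one class as a matrix
#'
#' @param epochs an `epoch_set`.
#' @param label `"movement"` or `"noise"`.
#' @return matrix of epochs (rows) by samples (columns).
#' @export
epoch_matrix <- function(epochs, label = NULL) {
  if (is.null(label)) return(epochs$samples)
  epochs$samples[epochs$meta$label == label, , drop = FALSE]
}
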
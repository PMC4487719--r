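#' Simulation configuration for synthetic MRCP recordings
#'
#' Bundles every tunable of the synthetic-recording generator. The defaults
#' reproduce the cue-based protocol the analysis pipeline assumes: two blocks
#' of 50 cued dorsiflexion trials (`f60`: 0.5 s ramp to 60% MVC; `s20`: 3 s
#' ramp to 20% MVC), EEG sampled at 500 Hz on the ten-channel 10-20 montage,
#' force sampled at 2000 Hz, and a movement-related cortical potential (MRCP)
#' modelled as a slow negativity starting 2 s before movement onset.
#'
#' @param n_trials_per_task number of trials per task (default 50).
#' @param tasks character vector of task ids, subset of `c("f60", "s20")`.
#' @param fs_eeg EEG sampling rate in Hz; must exceed 200 Hz so the 30-100 Hz
#'   gamma band is representable.
#' @param fs_force force sampling rate in Hz.
#' @param mrcp_peak_amplitude MRCP peak potential in microvolts (negative;
#'   default -10). Zero disables the MRCP entirely (null generator).
#' @param mrcp_rise_start time before movement onset, in seconds, at which the
#'   negativity begins (default 2).
#' @param mrcp_recovery_time duration in seconds of the post-onset return
#'   toward baseline (the shape after onset is never used by the analysis).
#' @param background_pink_sd standard deviation in microvolts of the 1/f
#'   (pink) background EEG per channel.
#' @param alpha_amplitude amplitude in microvolts of the background alpha
#'   oscillation per channel (random phase per channel).
#' @param alpha_freq alpha frequency in Hz.
#' @param channel_gains named numeric vector of per-channel MRCP scaling.
#'   Default peaks at Cz (1.0), 0.4 on the surrounding ring, 0 at FP1, so the
#'   large-Laplacian surrogate retains a net MRCP gain of 0.6.
#' @param inter_trial_interval seconds between consecutive cues; must be at
#'   least 10 s so the noise window (-5..-3 s) and force-baseline window
#'   (-4..-2 s) never overlap the previous trial.
#' @param force_noise_sd standard deviation of the additive force noise, as a
#'   fraction of MVC. The default 5e-4 models quiescent transducer noise.
#' @param onset_jitter_max upper bound, in seconds, of the uniform reaction
#'   delay between the visual cue and the true movement onset.
#' @param line_noise_amplitude amplitude in microvolts of an optional mains
#'   sinusoid added to every channel (default 0: no line component).
#' @param line_noise_freq mains frequency in Hz.
#' @param seed integer seed; when non-NULL, [generate_recording()] is fully
#'   deterministic.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [generate_recording()]
#' @export
sim_config <- function(n_trials_per_task = 50,
                       tasks = c("f60", "s20"),
                       fs_eeg = 500,
                       fs_force = 2000,
                       mrcp_peak_amplitude = -10,
                       mrcp_rise_start = 2,
                       mrcp_recovery_time = 1,
                       background_pink_sd = 2,
                       alpha_amplitude = 1,
                       alpha_freq = 10,
                       channel_gains = NULL,
                       inter_trial_interval = 10,
                       force_noise_sd = 5e-4,
                       onset_jitter_max = 0.3,
                       line_noise_amplitude = 0,
                       line_noise_freq = 50,
                       seed = NULL) {
  if (is.null(channel_gains)) {
    channel_gains <- c(FP1 = 0, F3 = 0.4, Fz = 0.4, F4 = 0.4, C3 = 0.4,
                       Cz = 1, C4 = 0.4, P3 = 0.4, Pz = 0.4, P4 = 0.4)
  }
  cfg <- list(n_trials_per_task = n_trials_per_task, tasks = tasks,
              fs_eeg = fs_eeg, fs_force = fs_force,
              mrcp_peak_amplitude = mrcp_peak_amplitude,
              mrcp_rise_start = mrcp_rise_start,
              mrcp_recovery_time = mrcp_recovery_time,
              background_pink_sd = background_pink_sd,
              alpha_amplitude = alpha_amplitude, alpha_freq = alpha_freq,
              channel_gains = channel_gains,
              inter_trial_interval = inter_trial_interval,
              force_noise_sd = force_noise_sd,
              onset_jitter_max = onset_jitter_max,
              line_noise_amplitude = line_noise_amplitude,
              line_noise_freq = line_noise_freq,
              seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_trials_per_task >= 1)
  if (!all(cfg$tasks %in% TASK_TABLE$task)) {
    stop("tasks must be a subset of: ", paste(TASK_TABLE$task, collapse = ", "))
  }
  if (cfg$fs_eeg <= 200) {
    stop("fs_eeg must exceed 200 Hz so the 30-100 Hz band is below Nyquist")
  }
  if (cfg$inter_trial_interval < 10) {
    stop("inter_trial_interval must be >= 10 s so the noise (-5..-3 s) and ",
         "baseline (-4..-2 s) windows fit inside each trial")
  }
  if (cfg$mrcp_rise_start <= 0) stop("mrcp_rise_start must be positive")
  if (cfg$mrcp_peak_amplitude > 0) {
    stop("mrcp_peak_amplitude is a negativity: it must be <= 0")
  }
  if (!setequal(names(cfg$channel_gains), EEG_CHANNELS)) {
    stop("channel_gains must be named with exactly: ",
         paste(EEG_CHANNELS, collapse = ", "))
  }
  if (cfg$onset_jitter_max < 0) stop("onset_jitter_max must be >= 0")
  invisible(cfg)
}

#' MRCP waveform model
#'
#' Deterministic morphology of the injected movement-related cortical
#' potential: zero before the negativity starts, a half-cosine ramp from 0
#' down to the (negative) peak amplitude at movement onset, then a half-cosine
#' recovery back to 0. The half-cosine has zero slope at both endpoints, so
#' the waveform joins the baseline smoothly.
#'
#' @param t_rel numeric vector of times in seconds relative to movement onset
#'   (negative = before onset).
#' @param cfg a [sim_config()].
#' @return potential in microvolts, same length as `t_rel`.
#' @examples
#' cfg <- sim_config()
#' mrcp_waveform(c(-3, -1, 0), cfg) # 0, half peak, full peak
#' @export
mrcp_waveform <- function(t_rel, cfg) {
  rise <- cfg$mrcp_rise_start
  rec <- cfg$mrcp_recovery_time
  a <- cfg$mrcp_peak_amplitude
  w <- numeric(length(t_rel))
  i <- t_rel > -rise & t_rel <= 0
  w[i] <- a * (1 - cos(pi * (t_rel[i] + rise) / rise)) / 2
  j <- t_rel > 0 & t_rel < rec
  w[j] <- a * (1 + cos(pi * t_rel[j] / rec)) / 2
  w
}

# Pink (1/f power) noise by spectral shaping of white noise: scale the FFT of
# a white draw by 1/sqrt(f) (DC bin zeroed), invert, then rescale to the
# requested sample standard deviation. Uses the current RNG stream.
pink_noise <- function(n, sd_target) {
  if (sd_target <= 0) return(numeric(n))
  x <- stats::rnorm(n)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) # bin distance from DC; symmetric so Hermitian is kept
  amp <- ifelse(f > 0, 1 / sqrt(f), 0)
  p <- Re(stats::fft(stats::fft(x) * amp, inverse = TRUE)) / n
  p / stats::sd(p) * sd_target
}

#' Generate background EEG
#'
#' One channel of background activity: pink (1/f power) noise scaled to
#' `background_pink_sd` plus an alpha-band sinusoid of amplitude
#' `alpha_amplitude` at `alpha_freq` with a random phase, plus an optional
#' mains sinusoid. Zero-mean by construction. Randomness is drawn from the
#' current R RNG stream, so callers control determinism with `set.seed()`.
#'
#' @param n_samples number of samples to generate.
#' @param cfg a [sim_config()].
#' @return numeric vector of length `n_samples`, in microvolts.
#' @export
generate_background <- function(n_samples, cfg) {
  stopifnot(n_samples > 0)
  t <- (0:(n_samples - 1)) / cfg$fs_eeg
  bg <- pink_noise(n_samples, cfg$background_pink_sd)
  if (cfg$alpha_amplitude > 0) {
    bg <- bg + cfg$alpha_amplitude *
      sin(2 * pi * cfg$alpha_freq * t + stats::runif(1, 0, 2 * pi))
  }
  if (cfg$line_noise_amplitude > 0) {
    bg <- bg + cfg$line_noise_amplitude *
      sin(2 * pi * cfg$line_noise_freq * t + stats::runif(1, 0, 2 * pi))
  }
  bg
}

# Noiseless force profile of one trial, evaluated at times `t` (seconds,
# recording clock). Linear ramp to the task target, a plateau, then a linear
# release back to rest. The linear ramp matches the cued constant-rate task
# and gives the onset a well-defined instantaneous slope.
force_ramp_shape <- function(task, onset, t) {
  p <- task_params(task)
  trel <- t - onset
  y <- numeric(length(t))
  i <- trel >= 0 & trel < p$ramp_dur
  y[i] <- p$target * trel[i] / p$ramp_dur
  i <- trel >= p$ramp_dur & trel < p$ramp_dur + p$plateau
  y[i] <- p$target
  i <- trel >= p$ramp_dur + p$plateau & trel < p$ramp_dur + p$plateau + p$release
  y[i] <- p$target * (1 - (trel[i] - p$ramp_dur - p$plateau) / p$release)
  y
}

#' Generate a noisy force trace for one trial
#'
#' Baseline at rest, a smooth monotone ramp starting at `onset` that reaches
#' 60% MVC after 0.5 s (`f60`) or 20% MVC after 3 s (`s20`), a plateau held
#' for 0.5 s, a release back to rest, and additive Gaussian noise of standard
#' deviation `force_noise_sd`.
#'
#' @param task `"f60"` or `"s20"`.
#' @param onset movement onset time in seconds on the trace clock.
#' @param cfg a [sim_config()].
#' @param n_samples number of samples; defaults to cover the whole trial plus
#'   2 s of rest.
#' @param t_start time of the first sample (default 0).
#' @return numeric vector, force as a fraction of MVC.
#' @export
generate_force_trace <- function(task, onset, cfg, n_samples = NULL,
                                 t_start = 0) {
  p <- task_params(task)
  if (is.null(n_samples)) {
    n_samples <- ceiling((onset - t_start + p$ramp_dur + p$plateau +
                            p$release + 2) * cfg$fs_force)
  }
  t <- t_start + (0:(n_samples - 1)) / cfg$fs_force
  y <- force_ramp_shape(task, onset, t)
  if (cfg$force_noise_sd > 0) {
    y <- y + stats::rnorm(n_samples, 0, cfg$force_noise_sd)
  }
  y
}

#' Generate a full synthetic recording
#'
#' Lays out `n_trials_per_task * length(tasks)` cued trials at
#' `inter_trial_interval` spacing, the tasks in randomised block order (one
#' block per task, as in a cued session). Each channel's EEG is background
#' activity plus the channel-gain-scaled MRCP aligned to the trial's true
#' onset. For `group = "real"` and `"attempted"` the true onset is the cue
#' time plus a uniform reaction delay and the force trace ramps accordingly;
#' for `group = "imaginary"` no movement is performed, the force trace stays
#' at baseline noise, and the true onset equals the cue time.
#'
#' @param cfg a [sim_config()]; if `cfg$seed` is non-NULL the recording is
#'   byte-identical across calls.
#' @param group one of `"real"`, `"imaginary"`, `"attempted"`.
#' @return An object of class `mrcp_recording`: a list with `eeg` (samples x
#'   10 matrix, microvolts, columns FP1, F3, Fz, F4, C3, Cz, C4, P3, Pz, P4),
#'   `fs_eeg`, `force` (fraction of MVC), `fs_force`, `cue_times` (s),
#'   `task_labels`, `true_onsets` (s, simulation ground truth), `group`.
#' @export
generate_recording <- function(cfg, group = c("real", "imaginary", "attempted")) {
  group <- match.arg(group)
  validate_sim_config(cfg)
  gen <- function() {
    iti <- cfg$inter_trial_interval
    block_order <- sample(cfg$tasks)
    task_labels <- rep(block_order, each = cfg$n_trials_per_task)
    n_trials <- length(task_labels)
    cue_times <- iti * seq_len(n_trials)
    duration <- iti * (n_trials + 1)
    jitter <- stats::runif(n_trials, 0, cfg$onset_jitter_max)
    true_onsets <- if (group == "imaginary") cue_times else cue_times + jitter

    n_eeg <- round(duration * cfg$fs_eeg)
    t_eeg <- (0:(n_eeg - 1)) / cfg$fs_eeg
    mrcp <- numeric(n_eeg)
    if (cfg$mrcp_peak_amplitude != 0) {
      span <- c(-cfg$mrcp_rise_start, cfg$mrcp_recovery_time)
      for (on in true_onsets) {
        i0 <- max(1L, floor((on + span[1]) * cfg$fs_eeg) + 1L)
        i1 <- min(n_eeg, ceiling((on + span[2]) * cfg$fs_eeg) + 1L)
        idx <- i0:i1
        mrcp[idx] <- mrcp[idx] + mrcp_waveform(t_eeg[idx] - on, cfg)
      }
    }
    eeg <- matrix(0, n_eeg, length(EEG_CHANNELS),
                  dimnames = list(NULL, EEG_CHANNELS))
    for (ch in EEG_CHANNELS) {
      eeg[, ch] <- generate_background(n_eeg, cfg) +
        cfg$channel_gains[[ch]] * mrcp
    }

    n_force <- round(duration * cfg$fs_force)
    t_force <- (0:(n_force - 1)) / cfg$fs_force
    force <- if (cfg$force_noise_sd > 0) {
      stats::rnorm(n_force, 0, cfg$force_noise_sd)
    } else numeric(n_force)
    if (group != "imaginary") {
      for (k in seq_len(n_trials)) {
        p <- task_params(task_labels[k])
        span <- p$ramp_dur + p$plateau + p$release
        i0 <- max(1L, floor(true_onsets[k] * cfg$fs_force) + 1L)
        i1 <- min(n_force, ceiling((true_onsets[k] + span) * cfg$fs_force) + 1L)
        idx <- i0:i1
        force[idx] <- force[idx] +
          force_ramp_shape(task_labels[k], true_onsets[k], t_force[idx])
      }
    }
    structure(list(eeg = eeg, fs_eeg = cfg$fs_eeg, force = force,
                   fs_force = cfg$fs_force, cue_times = cue_times,
                   task_labels = task_labels, true_onsets = true_onsets,
                   group = group),
              class = "mrcp_recording")
  }
  if (!is.null(cfg$seed)) withr::with_seed(cfg$seed, gen()) else gen()
}

#' @export
print.mrcp_recording <- function(x, ...) {
  cat("<mrcp_recording>", x$group, "movements\n")
  cat("  EEG:", nrow(x$eeg), "samples x", ncol(x$eeg), "channels @",
      x$fs_eeg, "Hz\n")
  cat("  force:", length(x$force), "samples @", x$fs_force, "Hz\n")
  tab <- table(x$task_labels)
  cat("  trials:", length(x$cue_times),
      sprintf("(%s)", paste(names(tab), tab, sep = ": ", collapse = ", ")),
      "\n")
  invisible(x)
}
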
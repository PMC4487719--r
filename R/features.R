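#' Temporal features of a 2 s surrogate epoch
#'
#' Computed from the 0.05-10 Hz band-passed path. In `executed` mode, six
#' features: (1) time of maximum negativity (seconds from epoch start, ties
#' to the earliest sample), (2) mean amplitude, (3, 4) slope and intercept of
#' an ordinary least-squares line over the epoch, (5, 6) slope and intercept
#' of an OLS line over the final 0.5 s (the 0.5 s preceding movement onset).
#' In `imagery` mode, five features: (1), (2), both slopes, and the mean
#' amplitude of the final 0.5 s; intercepts are excluded. The time axis of
#' all regressions is in seconds relative to epoch start.
#'
#' The endpoint of the full-epoch regression is a switch: `"epoch_end"`
#' (default; the detection point coincides with the epoch's end at movement
#' onset) or `"max_negativity"` (regression from the start up to the minimum
#' sample).
#'
#' @param x numeric epoch (temporal path), typically 2 s long.
#' @param fs sampling rate in Hz.
#' @param mode `"executed"` (6 features) or `"imagery"` (5 features).
#' @param regression_end endpoint of the full-epoch regression.
#' @return named numeric vector of features.
#' @export
temporal_features <- function(x, fs, mode = c("executed", "imagery"),
                              regression_end = c("epoch_end", "max_negativity")) {
  mode <- match.arg(mode)
  regression_end <- match.arg(regression_end)
  n <- length(x)
  if (n < 2) stop("epoch too short")
  t <- (0:(n - 1)) / fs
  imin <- which.min(x) # ties resolved to the earliest sample
  end_idx <- if (regression_end == "epoch_end") n else max(imin, 2L)
  fit_full <- ols_line(t[1:end_idx], x[1:end_idx])
  final <- t >= n / fs - 0.5
  fit_final <- ols_line(t[final], x[final])
  if (mode == "executed") {
    c(t_max_negativity = t[imin],
      mean_amp = mean(x),
      slope = fit_full[["slope"]],
      intercept = fit_full[["intercept"]],
      slope_final = fit_final[["slope"]],
      intercept_final = fit_final[["intercept"]])
  } else {
    c(t_max_negativity = t[imin],
      mean_amp = mean(x),
      slope = fit_full[["slope"]],
      slope_final = fit_final[["slope"]],
      mean_final = mean(x[final]))
  }
}

ols_line <- function(t, x) {
  mt <- mean(t); mx <- mean(x)
  slope <- sum((t - mt) * (x - mx)) / sum((t - mt)^2)
  c(slope = slope, intercept = mx - slope * mt)
}

#' Welch power spectral density estimate
#'
#' Splits the series into Hamming-windowed segments of `seg_len` samples with
#' `overlap` fractional overlap and averages the window-power-normalised
#' periodograms (one-sided density, power per Hz). The default segment
#' length of one second gives 1 Hz resolution, so three segments per 2 s
#' epoch at 50% overlap.
#'
#' @param x numeric series (spectral path epoch).
#' @param fs sampling rate in Hz.
#' @param seg_len segment length in samples (default `round(fs)`, capped at
#'   the series length).
#' @param overlap fractional overlap between segments (default 0.5).
#' @return list with `freq` (Hz) and `psd` (microvolts squared per Hz).
#' @export
welch_psd <- function(x, fs, seg_len = NULL, overlap = 0.5) {
  n <- length(x)
  if (is.null(seg_len)) seg_len <- min(n, round(fs))
  if (seg_len > n) stop("seg_len exceeds the epoch length")
  step <- max(1, round(seg_len * (1 - overlap)))
  starts <- seq(1, n - seg_len + 1, by = step)
  w <- signal::hamming(seg_len)
  u <- sum(w^2) # window power normalisation
  nf <- floor(seg_len / 2) + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1)] * w
    p <- Mod(stats::fft(seg)[1:nf])^2 / (fs * u)
    # one-sided: double every bin except DC and (for even seg_len) Nyquist
    top <- if (seg_len %% 2 == 0) nf - 1 else nf
    if (top >= 2) p[2:top] <- 2 * p[2:top]
    acc <- acc + p
  }
  list(freq = (0:(nf - 1)) * fs / seg_len, psd = acc / length(starts))
}

#' Mean power in a frequency band
#'
#' Mean of the PSD over bins with `lo <= f < hi` (half-open, so adjacent
#' bands sharing an edge never double-count a bin); set `include_upper` for
#' the final band so its upper edge is included.
#'
#' @param freq,psd as returned by [welch_psd()].
#' @param lo,hi band edges in Hz.
#' @param include_upper include bins at exactly `hi`?
#' @return scalar mean power density.
#' @export
band_power <- function(freq, psd, lo, hi, include_upper = FALSE) {
  stopifnot(lo < hi, lo >= 0)
  sel <- freq >= lo & (freq < hi | (include_upper & freq <= hi))
  if (!any(sel)) {
    stop("no PSD bins inside [", lo, ", ", hi, ") Hz: resolution too coarse")
  }
  mean(psd[sel])
}

#' Default spectral bands
#'
#' The five canonical ranges: 0-4 (delta), 4-8 (mu), 8-13 (alpha), 13-30
#' (beta) and 30-100 Hz (gamma).
#'
#' @return data.frame with columns `name`, `lo`, `hi`.
#' @export
default_bands <- function() {
  data.frame(name = c("delta", "mu", "alpha", "beta", "gamma"),
             lo = c(0, 4, 8, 13, 30),
             hi = c(4, 8, 13, 30, 100),
             stringsAsFactors = FALSE)
}

#' Spectral features of an epoch
#'
#' The mean Welch band power in each of the five default bands, computed on
#' the 0.05 Hz high-passed path.
#'
#' @param x numeric epoch (spectral path).
#' @param fs sampling rate in Hz.
#' @param bands band definition data.frame (see [default_bands()]).
#' @param seg_len,overlap passed to [welch_psd()].
#' @return named numeric vector of band powers.
#' @export
spectral_features <- function(x, fs, bands = default_bands(),
                              seg_len = NULL, overlap = 0.5) {
  stopifnot(all(bands$lo < bands$hi), all(bands$hi <= fs / 2))
  p <- welch_psd(x, fs, seg_len = seg_len, overlap = overlap)
  vals <- vapply(seq_len(nrow(bands)), function(i) {
    band_power(p$freq, p$psd, bands$lo[i], bands$hi[i],
               include_upper = i == nrow(bands))
  }, numeric(1))
  names(vals) <- bands$name
  vals
}

#' Feature table for an epoch set
#'
#' Applies [temporal_features()] or [spectral_features()] to every epoch and
#' returns the epoch metadata alongside the named feature columns.
#'
#' @param epochs an `epoch_set`.
#' @param type `"temporal"` or `"spectral"`; must match the set's path.
#' @param ... passed on to the per-epoch feature function.
#' @return data.frame: `label`, `task`, `t0`, `trial`, then feature columns.
#' @export
extract_features <- function(epochs, type = c("temporal", "spectral"), ...) {
  type <- match.arg(type)
  if (epochs$path != type) {
    stop(type, " features must be computed on the ", type, " path, not the ",
         epochs$path, " path")
  }
  fun <- if (type == "temporal") {
    function(x) temporal_features(x, epochs$fs, ...)
  } else {
    function(x) spectral_features(x, epochs$fs, ...)
  }
  feats <- t(apply(epochs$samples, 1, fun))
  stopifnot(all(is.finite(feats)))
  cbind(epochs$meta, as.data.frame(feats))
}
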
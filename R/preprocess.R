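# AED-style ECG conditioning: mean subtraction, moving-average smoothing,
# 1-30 Hz bandpass (the typical AED monitoring bandwidth).

#' Preprocessing configuration
#'
#' @param ma_window Moving-average window in samples; odd, >= 1. The default
#'   5-point window at 250 Hz (20 ms) smooths high-frequency noise without
#'   blunting QRS complexes.
#' @param band_low,band_high Bandpass corner frequencies in Hz (-3 dB points
#'   of the Butterworth design).
#' @param filter_order Butterworth order of the bandpass (applied
#'   forward-backward, so the effective attenuation is doubled).
#' @param zero_phase Apply the bandpass forward-backward
#'   ([signal::filtfilt()]) so ECG morphology is not phase-distorted.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(ma_window = 5L, band_low = 1, band_high = 30,
                              filter_order = 4L, zero_phase = TRUE) {
  if (ma_window < 1L || ma_window %% 2L == 0L)
    stop("`ma_window` must be odd and >= 1")
  if (!(band_low > 0 && band_low < band_high))
    stop("need 0 < band_low < band_high")
  structure(list(ma_window = as.integer(ma_window), band_low = band_low,
                 band_high = band_high, filter_order = as.integer(filter_order),
                 zero_phase = isTRUE(zero_phase)),
            class = "preprocess_config")
}

#' Subtract the signal mean
#'
#' @param x Non-empty numeric vector.
#' @return `x - mean(x)`.
#' @export
remove_mean <- function(x) {
  if (length(x) == 0L) stop("`x` must be non-empty")
  x - mean(x)
}

#' Moving-average filter
#'
#' Centered moving average with reflect padding at the edges; output length
#' equals input length.
#'
#' @param x Numeric vector.
#' @param w Odd window width in samples, `1 <= w <= length(x)`.
#' @return Smoothed vector, same length as `x`.
#' @export
moving_average <- function(x, w) {
  if (w < 1L || w %% 2L == 0L) stop("`w` must be odd and positive")
  if (w > length(x)) stop("`w` must not exceed length(x)")
  if (w == 1L) return(as.numeric(x))
  h <- (w - 1L) %/% 2L
  xp <- c(rev(x[2L:(h + 1L)]), x, rev(x[(length(x) - h):(length(x) - 1L)]))
  as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2)[(h + 1L):(h + length(x))])
}

#' Bandpass filter in the AED monitoring band
#'
#' Butterworth bandpass (default 1-30 Hz, order 4) applied zero-phase
#' (forward-backward) by default.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz; must exceed twice the upper corner.
#' @param cfg A [preprocess_config()].
#' @return Filtered vector, same length as `x`.
#' @export
bandpass_1_30 <- function(x, fs, cfg = preprocess_config()) {
  if (fs <= 2 * cfg$band_high)
    stop("`fs` must exceed twice the upper band edge")
  if (length(x) <= 3L * cfg$filter_order)
    stop("input too short for the bandpass filter")
  bt <- signal::butter(cfg$filter_order,
                       c(cfg$band_low, cfg$band_high) / (fs / 2),
                       type = "pass")
  # reflect-pad to suppress start-up transients at the record edges
  np <- min(length(x) - 1L, as.integer(3 * fs))
  xp <- c(2 * x[1L] - rev(x[2L:(np + 1L)]), x,
          2 * x[length(x)] - rev(x[(length(x) - np):(length(x) - 1L)]))
  y <- if (cfg$zero_phase) signal::filtfilt(bt, xp) else signal::filter(bt, xp)
  as.numeric(y[(np + 1L):(np + length(x))])
}

#' Full AED conditioning chain
#'
#' Applies, in order: mean subtraction, moving-average smoothing, and the
#' 1-30 Hz bandpass. This removes baseline drift and respiration artifact
#' below the band and power-line/muscle noise above it.
#'
#' The chain guarantees a zero-DC output: the bandpass suppresses the
#' asymptotic DC response but not the finite-sample mean of a noisy record,
#' so the residual mean is subtracted after filtering.
#'
#' @inheritParams bandpass_1_30
#' @return Conditioned signal, same length as `x`, with zero mean.
#' @export
preprocess_ecg <- function(x, fs, cfg = preprocess_config()) {
  remove_mean(
    bandpass_1_30(moving_average(remove_mean(x), cfg$ma_window), fs, cfg))
}
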
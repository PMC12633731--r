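#' EMG channel container
#'
#' One muscle's voltage trace with its sampling rate, a sync offset to the
#' video clock, and a quiet window (an inactive portion of the record used
#' to estimate the baseline).
#'
#' @param samples Numeric voltage series.
#' @param fs Sampling rate, samples per second (10 kHz in this study).
#' @param fish Fish identifier.
#' @param muscle Muscle label (`Abd`, `Add`, `Cmt`, `Zpt`).
#' @param sync_offset_s Offset added to convert channel time to video time.
#' @param quiet_window Length-2 numeric `(t0, t1)` in seconds marking an
#'   inactive portion of the trace; must lie inside the record.
#' @return An `emg_channel` object.
#' @export
emg_channel <- function(samples, fs, fish = NA, muscle = NA,
                        sync_offset_s = 0, quiet_window = NULL) {
  stopifnot(fs > 0, is.numeric(samples))
  dur <- length(samples) / fs
  if (!is.null(quiet_window)) {
    stopifnot(length(quiet_window) == 2, quiet_window[1] < quiet_window[2])
    if (quiet_window[1] < 0 || quiet_window[2] > dur)
      stop("quiet_window must lie inside the record (0, ", round(dur, 3), ")")
  }
  structure(list(samples = samples, fs = fs, fish = fish, muscle = muscle,
                 sync_offset_s = sync_offset_s, quiet_window = quiet_window),
            class = "emg_channel")
}

#' @export
print.emg_channel <- function(x, ...) {
  cat(sprintf("EMG channel %s/%s: %d samples @ %g Hz (%.2f s)\n",
              x$fish, x$muscle, length(x$samples), x$fs,
              length(x$samples) / x$fs))
  invisible(x)
}

#' Centre an EMG trace on its quiet-window baseline
#'
#' Subtracts the mean signal over an inactive portion of the trace so the
#' centred record fluctuates around zero. A quiet window shorter than
#' 50 ms is rejected as an unreliable baseline.
#'
#' @param channel An [emg_channel()] with a `quiet_window`.
#' @return The channel with centred samples (and `$baseline` recorded).
#' @export
center_signal <- function(channel) {
  stopifnot(inherits(channel, "emg_channel"))
  qw <- channel$quiet_window
  if (is.null(qw)) stop("channel has no quiet_window")
  if (qw[2] - qw[1] < 0.05)
    stop("quiet window shorter than 50 ms: baseline unreliable")
  i0 <- floor(qw[1] * channel$fs) + 1L
  i1 <- min(length(channel$samples), ceiling(qw[2] * channel$fs))
  baseline <- mean(channel$samples[i0:i1])
  channel$samples <- channel$samples - baseline
  channel$baseline <- baseline
  channel
}

#' Band-pass filter an EMG series (40-4000 Hz)
#'
#' Linear-phase FIR band-pass (Hamming-windowed, 1024th order) applied via
#' FFT convolution with group-delay compensation, so the output is
#' zero-phase. Requires `fs > 2 * high`.
#'
#' @param x Numeric series.
#' @param fs Sampling rate.
#' @param low,high Band edges in Hz.
#' @param order FIR order (number of taps minus one).
#' @return Filtered series, same length as `x`.
#' @export
bandpass_filter <- function(x, fs, low = 40, high = 4000, order = 1024) {
  if (fs <= 2 * high)
    stop("sampling rate ", fs, " must exceed twice the upper band edge ", high)
  h <- signal::fir1(order, c(low, high) / (fs / 2), type = "pass")
  delay <- order / 2
  y <- signal::fftfilt(h, c(x, numeric(order)))
  y[(delay + 1):(delay + length(x))]
}

#' Moving RMS envelope
#'
#' Centred moving root-mean-square with a default 400-sample window
#' (40 ms at 10 kHz). Edge windows are truncated to the available samples,
#' so a constant input returns its absolute value everywhere.
#'
#' @param x Numeric series.
#' @param window Window length in samples (>= 1, <= length of `x`).
#' @return Non-negative envelope, same length as `x`.
#' @export
rms_envelope <- function(x, window = 400) {
  n <- length(x)
  stopifnot(window >= 1, window <= n)
  half_lo <- floor((window - 1) / 2)
  half_hi <- window - 1 - half_lo
  cs <- c(0, cumsum(x^2))
  i <- seq_len(n)
  lo <- pmax(1L, i - half_lo)
  hi <- pmin(n, i + half_hi)
  sqrt((cs[hi + 1] - cs[lo]) / (hi - lo + 1))
}
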
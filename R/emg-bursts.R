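#' Burst detection and normalized burst metrics
#'
#' Muscle activity onsets and offsets are the crossings of the moving-RMS
#' envelope through 25% of its whole-record mean. The preliminary burst
#' train is cleaned with a physiological rate rule: a muscle cannot switch
#' on and off faster than 100 Hz, so inter-burst gaps shorter than 10 ms
#' are merged and remaining bursts shorter than 10 ms are dropped (in that
#' order). Metrics are computed from the centred (band-passed) signal:
#' burst duration, duty factor, rectified integrated area as a percentage
#' of the theoretical maximum (channel maximum amplitude times burst
#' duration), and maximum amplitude (mean of the top 5% of rectified
#' samples) as a percentage of the channel maximum.
#'
#' @name emg_bursts
NULL

#' Detect bursts from an RMS envelope
#'
#' @param envelope Non-negative envelope series.
#' @param fs Sampling rate.
#' @param threshold_frac Threshold as a fraction of the envelope mean
#'   (default 0.25).
#' @param threshold Absolute threshold overriding `threshold_frac`
#'   (e.g. for a per-cycle baseline).
#' @return Data frame with `onset_s`, `offset_s`, sorted and
#'   non-overlapping; empty for an all-zero envelope.
#' @export
detect_bursts <- function(envelope, fs, threshold_frac = 0.25,
                          threshold = NULL) {
  stopifnot(all(envelope >= 0))
  if (is.null(threshold)) threshold <- threshold_frac * mean(envelope)
  if (threshold <= 0 || all(envelope <= threshold))
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0)))
  above <- envelope > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on_idx <- starts[r$values]
  off_idx <- ends[r$values]
  data.frame(onset_s = (on_idx - 1) / fs, offset_s = off_idx / fs)
}

#' Apply the 100 Hz physiological rate rule
#'
#' Merges inter-burst gaps shorter than `min_gap_s`, then removes bursts
#' shorter than `min_dur_s` (a full on-off cycle at 100 Hz lasts 10 ms).
#' Idempotent: applying the filter twice equals applying it once.
#'
#' @param bursts Data frame with `onset_s`, `offset_s`, sorted.
#' @param min_gap_s Gap threshold in seconds (default 0.010).
#' @param min_dur_s Duration threshold in seconds (default 0.010).
#' @return Filtered burst data frame.
#' @export
rate_filter <- function(bursts, min_gap_s = 0.010, min_dur_s = 0.010) {
  if (nrow(bursts) == 0) return(bursts)
  stopifnot(!is.unsorted(bursts$onset_s))
  on <- bursts$onset_s[1]; off <- bursts$offset_s[1]
  O <- c(); F <- c()
  for (i in seq_len(nrow(bursts))[-1]) {
    if (bursts$onset_s[i] - off < min_gap_s) {
      off <- max(off, bursts$offset_s[i])
    } else {
      O <- c(O, on); F <- c(F, off)
      on <- bursts$onset_s[i]; off <- bursts$offset_s[i]
    }
  }
  O <- c(O, on); F <- c(F, off)
  keep <- (F - O) >= min_dur_s
  data.frame(onset_s = O[keep], offset_s = F[keep])
}

# Sample index range covering [t0, t1]: sample k sits at time (k - 1) / fs;
# the range runs from the last sample at or before t0 to the last sample at
# or before t1, so grid-aligned windows are closed intervals and a constant
# signal integrates exactly to value * (t1 - t0).
window_idx <- function(n, fs, t0, t1) {
  i0 <- max(1L, floor(t0 * fs + 1e-9) + 1L)
  i1 <- min(n, floor(t1 * fs + 1e-9) + 1L)
  c(i0, i1)
}

# Trapezoid integral of |x| over [t0, t1] on the sample grid.
rect_integral <- function(x, fs, t0, t1) {
  i <- window_idx(length(x), fs, t0, t1)
  if (i[2] <= i[1]) return(0)
  r <- abs(x[i[1]:i[2]])
  sum((r[-1] + r[-length(r)]) / 2) / fs
}

# Rectified samples of x within [t0, t1].
rect_samples <- function(x, fs, t0, t1) {
  i <- window_idx(length(x), fs, t0, t1)
  if (i[2] < i[1]) return(numeric(0))
  abs(x[i[1]:i[2]])
}

top5_mean <- function(r) {
  if (length(r) == 0) return(NA_real_)
  k <- max(1L, ceiling(0.05 * length(r)))
  mean(sort(r, decreasing = TRUE)[seq_len(k)])
}

#' Per-burst amplitude and rectified area
#'
#' @param centered Centred (band-passed) signal.
#' @param fs Sampling rate.
#' @param bursts Data frame with `onset_s`, `offset_s`.
#' @return The burst table with `duration_s`, `amp_top5` (mean of the top
#'   5% of rectified samples within the burst) and `ria_raw` (trapezoid
#'   integral of the rectified signal, V s).
#' @export
burst_amplitudes <- function(centered, fs, bursts) {
  bursts$duration_s <- bursts$offset_s - bursts$onset_s
  bursts$amp_top5 <- vapply(seq_len(nrow(bursts)), function(i) {
    top5_mean(rect_samples(centered, fs, bursts$onset_s[i], bursts$offset_s[i]))
  }, numeric(1))
  bursts$ria_raw <- vapply(seq_len(nrow(bursts)), function(i) {
    rect_integral(centered, fs, bursts$onset_s[i], bursts$offset_s[i])
  }, numeric(1))
  bursts
}

#' Channel normalization constant
#'
#' The highest maximum burst amplitude recorded on a fish x muscle channel
#' across all trials and both behaviours; every amplitude percentage on
#' that channel is expressed relative to it. Accepts either a burst table
#' (its `amp_top5` column, or `amp_raw` for scope-level pooled amplitudes)
#' or a bare numeric vector of amplitude values. Normalizing against the
#' maximum of the same amplitude quantity being reported keeps every
#' percentage in \[0, 100\] with equality attained on the channel.
#'
#' @param bursts Data frame with an `amp_top5` (or `amp_raw`) column, or a
#'   numeric vector of amplitudes (>= 1 value).
#' @return List with `max_amp`.
#' @export
channel_normalization <- function(bursts) {
  amps <- if (is.data.frame(bursts)) {
    if (!is.null(bursts$amp_raw)) bursts$amp_raw else bursts$amp_top5
  } else as.numeric(bursts)
  amps <- amps[is.finite(amps)]
  if (length(amps) == 0)
    stop("no bursts: channel normalization undefined")
  list(max_amp = max(amps))
}

#' Per-cycle, per-phase burst metrics
#'
#' For each scope (full cycle, propulsive phase, recovery phase), bursts
#' are clipped to the scope and summarized: total activation duration, duty
#' factor (% of scope duration), amplitude percentage (top 5% of rectified
#' samples pooled across the scope's bursts, relative to the channel
#' maximum), RIA percentage (summed rectified area over summed theoretical
#' maxima `max_amp * duration`), burst count, and polar timings of burst
#' onsets/offsets falling inside the cycle.
#'
#' @param centered Centred (band-passed) signal.
#' @param fs Sampling rate.
#' @param bursts Data frame with `onset_s`, `offset_s` (rate-filtered).
#' @param cycle List with `t_start`, `t_mid`, `t_end`.
#' @param norm List with `max_amp` from [channel_normalization()], or
#'   `NULL` to report only the unnormalized `amp_raw` / `ria_raw` (used in
#'   the first pass, before the channel maximum is known).
#' @return Data frame with one row per scope (`full_cycle`, `propulsion`,
#'   `recovery`) and columns `activation_duration_s`, `duty_factor_pct`,
#'   `amp_raw` (pooled top-5% rectified amplitude, V), `ria_raw` (V s),
#'   `ria_pct`, `amp_pct`, `n_bursts`; attribute `"timings"` holds a data
#'   frame of polar onset/offset timings.
#' @export
burst_metrics <- function(centered, fs, bursts, cycle, norm = NULL) {
  scopes <- list(full_cycle = c(cycle$t_start, cycle$t_end),
                 propulsion = c(cycle$t_start, cycle$t_mid),
                 recovery = c(cycle$t_mid, cycle$t_end))
  rows <- lapply(names(scopes), function(sc) {
    lim <- scopes[[sc]]
    clip_on <- pmax(bursts$onset_s, lim[1])
    clip_off <- pmin(bursts$offset_s, lim[2])
    sel <- which(clip_off > clip_on)
    scope_dur <- lim[2] - lim[1]
    if (length(sel) == 0) {
      return(data.frame(scope = sc, activation_duration_s = 0,
                        duty_factor_pct = 0, amp_raw = NA_real_,
                        ria_raw = NA_real_, ria_pct = NA_real_,
                        amp_pct = NA_real_, n_bursts = 0L))
    }
    act <- sum(clip_off[sel] - clip_on[sel])
    pooled <- unlist(lapply(sel, function(i)
      rect_samples(centered, fs, clip_on[i], clip_off[i])))
    ria <- sum(vapply(sel, function(i)
      rect_integral(centered, fs, clip_on[i], clip_off[i]), numeric(1)))
    data.frame(scope = sc, activation_duration_s = act,
               duty_factor_pct = 100 * act / scope_dur,
               amp_raw = top5_mean(pooled), ria_raw = ria,
               ria_pct = NA_real_, amp_pct = NA_real_,
               n_bursts = length(sel))
  })
  out <- do.call(rbind, rows)
  if (!is.null(norm)) out <- normalize_emg_summary(out, norm)
  in_cycle <- function(t) t >= cycle$t_start & t < cycle$t_end
  timings <- data.frame(
    event = c(rep("onset", sum(in_cycle(bursts$onset_s))),
              rep("offset", sum(in_cycle(bursts$offset_s)))),
    deg = c(to_polar_timing(bursts$onset_s[in_cycle(bursts$onset_s)], cycle),
            to_polar_timing(bursts$offset_s[in_cycle(bursts$offset_s)], cycle))
  )
  attr(out, "timings") <- timings
  out
}

#' Run the full EMG pipeline on one channel
#'
#' Centre, band-pass, denoise, envelope, detect, rate-filter; burst
#' amplitudes and rectified areas are computed from the centred
#' band-passed signal (the denoised signal is used only for detection).
#'
#' @param channel An [emg_channel()].
#' @param window RMS window in samples (default 400).
#' @param threshold_frac Envelope threshold fraction (default 0.25).
#' @param min_gap_s,min_dur_s Rate-filter thresholds (default 10 ms).
#' @param denoise Logical; set `FALSE` to skip wavelet denoising (the
#'   envelope is then computed from the band-passed signal).
#' @return List with `bursts` (with amplitudes), `centered` (band-passed
#'   centred samples), `envelope`, `fs`.
#' @export
process_channel <- function(channel, window = 400, threshold_frac = 0.25,
                            min_gap_s = 0.010, min_dur_s = 0.010,
                            denoise = TRUE) {
  ch <- center_signal(channel)
  centered <- bandpass_filter(ch$samples, ch$fs)
  det <- if (denoise) denoise_emg(centered) else centered
  env <- rms_envelope(det, window)
  bursts <- detect_bursts(env, ch$fs, threshold_frac)
  bursts <- rate_filter(bursts, min_gap_s, min_dur_s)
  bursts <- burst_amplitudes(centered, ch$fs, bursts)
  list(bursts = bursts, centered = centered, envelope = env, fs = ch$fs)
}

#' Normalize scope-level amplitude and RIA against a channel maximum
#'
#' `amp_pct = 100 * amp_raw / max_amp`; `ria_pct = 100 * ria_raw /
#' (max_amp * activation_duration)`, the percentage of the theoretical
#' maximum (channel maximum amplitude sustained for the whole active
#' time).
#'
#' @param summary Data frame from [burst_metrics()] / [emg_cycle_summary()].
#' @param norm List with `max_amp`.
#' @return The summary with `amp_pct` and `ria_pct` filled in.
#' @export
normalize_emg_summary <- function(summary, norm) {
  stopifnot(norm$max_amp > 0)
  summary$amp_pct <- 100 * summary$amp_raw / norm$max_amp
  summary$ria_pct <- 100 * summary$ria_raw /
    (norm$max_amp * summary$activation_duration_s)
  summary
}

#' Per-cycle EMG summary table for one processed channel
#'
#' @param processed Output of [process_channel()].
#' @param cycles Data frame with `t_start`, `t_mid`, `t_end` (and
#'   optionally `cycle`, `behaviour`).
#' @param norm List with `max_amp` (channel normalization across the whole
#'   fish x muscle channel), or `NULL` for a first unnormalized pass.
#' @return List with `summary` (cycle x scope rows) and `timings` (polar
#'   onset/offset angles per cycle).
#' @export
emg_cycle_summary <- function(processed, cycles, norm = NULL) {
  rows <- list(); tim <- list()
  for (i in seq_len(nrow(cycles))) {
    cyc <- as.list(cycles[i, ])
    m <- burst_metrics(processed$centered, processed$fs, processed$bursts,
                       cyc, norm)
    m$cycle <- if (!is.null(cyc$cycle)) cyc$cycle else i
    if (!is.null(cyc$behaviour)) m$behaviour <- cyc$behaviour
    rows[[i]] <- m
    ti <- attr(m, "timings")
    if (nrow(ti) > 0) {
      ti$cycle <- m$cycle[1]
      if (!is.null(cyc$behaviour)) ti$behaviour <- cyc$behaviour
      tim[[i]] <- ti
    }
  }
  list(summary = do.call(rbind, rows),
       timings = if (length(tim)) do.call(rbind, tim)
       else data.frame(event = character(0), deg = numeric(0)))
}
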
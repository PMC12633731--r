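#' Simulate one trial (fish x behaviour): EMG, trajectories, ground truth
#'
#' Builds a consecutive train of stroke cycles with behaviour-specific
#' durations, then generates (a) multi-channel EMG — baseline Gaussian noise
#' with bursts of band-limited (40-4000 Hz) noise under a trapezoidal
#' amplitude envelope (5 ms rise/fall), scheduled per muscle with von Mises
#' timing jitter on the cycle circle, plus optional low-frequency movement
#' artifacts — and (b) smooth 3D landmark trajectories whose per-cycle
#' extrema, timings, velocity summaries and path lengths are recorded as
#' ground truth (extrema and timings in closed form, path lengths by fine
#' quadrature of the analytic curve).
#'
#' Bursts that overlap after jitter are merged in the ground truth with a
#' warning.
#'
#' @param config A [gait_sim_config()].
#' @param fish Fish identifier (integer).
#' @param behaviour One of `config$behaviours`.
#' @param n_cycles Number of stroke cycles (default from config).
#' @param seed Integer seed (default derived from `config$seed`, fish and
#'   behaviour so every trial differs but the study is reproducible).
#' @return List with `fish`, `behaviour`, `cycles` (data frame:
#'   `t_start`, `t_mid`, `t_end`, `behaviour`), `channels` (named list of
#'   [emg_channel()] objects), `trajectories` (data frame: `frame`,
#'   `time_s`, `landmark`, `x`, `y`, `z`), and `truth` (list: `bursts`,
#'   `kinematics` per cycle).
#' @export
simulate_trial <- function(config, fish = 1L, behaviour = "swimming",
                           n_cycles = config$cycles_per_fish,
                           seed = trial_seed(config$seed, fish, behaviour)) {
  stopifnot(inherits(config, "gait_sim_config"))
  if (!behaviour %in% config$behaviours)
    stop("unknown behaviour '", behaviour, "'")
  set.seed(seed)

  cd <- config$cycle_duration[[behaviour]]
  pf <- config$propulsion_fraction[[behaviour]]
  lead <- 0.5
  durs <- pmax(cd[["mean"]] / 2, rnorm(n_cycles, cd[["mean"]], cd[["sd"]]))
  t_start <- lead + c(0, cumsum(durs[-n_cycles]))
  cycles <- data.frame(
    cycle = seq_len(n_cycles),
    t_start = t_start,
    t_mid = t_start + pf * durs,
    t_end = t_start + durs,
    behaviour = behaviour
  )
  total_dur <- lead + sum(durs) + 0.5

  emg <- simulate_emg_channels(config, fish, behaviour, cycles, total_dur)
  kin <- simulate_trajectories(config, behaviour, cycles, total_dur)

  list(fish = fish, behaviour = behaviour, cycles = cycles,
       channels = emg$channels, trajectories = kin$trajectories,
       truth = list(bursts = emg$truth_bursts, kinematics = kin$truth))
}

#' @rdname simulate_trial
#' @export
generate_emg <- function(config, fish = 1L, behaviour = "swimming",
                         n_cycles = config$cycles_per_fish,
                         seed = trial_seed(config$seed, fish, behaviour)) {
  tr <- simulate_trial(config, fish, behaviour, n_cycles, seed)
  list(channels = tr$channels, cycles = tr$cycles,
       truth_bursts = tr$truth$bursts)
}

#' @rdname simulate_trial
#' @export
generate_kinematics <- function(config, fish = 1L, behaviour = "swimming",
                                n_cycles = config$cycles_per_fish,
                                seed = trial_seed(config$seed, fish, behaviour)) {
  tr <- simulate_trial(config, fish, behaviour, n_cycles, seed)
  list(trajectories = tr$trajectories, cycles = tr$cycles,
       truth = tr$truth$kinematics)
}

# ---- EMG generation ---------------------------------------------------

simulate_emg_channels <- function(config, fish, behaviour, cycles, total_dur) {
  fs <- config$fs_emg
  n <- round(total_dur * fs)
  tt <- (seq_len(n) - 1) / fs
  sched <- config$burst_schedule[config$burst_schedule$behaviour == behaviour, ,
                                 drop = FALSE]
  muscles <- unique(sched$muscle)
  channels <- list()
  truth_all <- list()

  for (mus in muscles) {
    rows <- sched[sched$muscle == mus, , drop = FALSE]
    onsets <- c(); offsets <- c(); amps <- c()
    for (i in seq_len(nrow(cycles))) {
      Ti <- cycles$t_end[i] - cycles$t_start[i]
      for (j in seq_len(nrow(rows))) {
        jit <- if (config$timing_kappa > 0)
          deg2rad(rvonmises(1, 0, config$timing_kappa)) / (2 * pi) else 0
        if (jit > 0.5) jit <- jit - 1   # map to (-0.5, 0.5]
        onsets <- c(onsets, cycles$t_start[i] + (rows$onset_phase[j] + jit) * Ti)
        offsets <- c(offsets, cycles$t_start[i] + (rows$offset_phase[j] + jit) * Ti)
        amps <- c(amps, rows$amp[j])
      }
    }
    ord <- order(onsets)
    onsets <- onsets[ord]; offsets <- offsets[ord]; amps <- amps[ord]
    merged <- merge_scheduled_bursts(onsets, offsets, amps)
    if (attr(merged, "n_merged") > 0)
      warning(sprintf("%s/%s %s: %d overlapping scheduled bursts merged",
                      fish, behaviour, mus, attr(merged, "n_merged")))

    x <- if (config$noise_sd > 0) rnorm(n, 0, config$noise_sd) else numeric(n)
    for (k in seq_len(nrow(merged))) {
      i0 <- max(1L, floor(merged$onset_s[k] * fs) + 1L)
      i1 <- min(n, ceiling(merged$offset_s[k] * fs))
      if (i1 <= i0) next
      x[i0:i1] <- x[i0:i1] +
        burst_carrier(i1 - i0 + 1L, fs, merged$amp[k])
    }
    if (config$artifact_rate > 0) {
      n_art <- rpois(1, config$artifact_rate * total_dur)
      for (k in seq_len(n_art)) {
        centre <- runif(1, 0, total_dur)
        f <- runif(1, 2, 10)
        w <- 0.15
        x <- x + config$artifact_amp *
          sin(2 * pi * f * (tt - centre)) * exp(-(tt - centre)^2 / (2 * w^2))
      }
    }
    # DC offset exercises the centering step; vanishes in the noiseless case
    x <- x + 0.3 * config$noise_sd

    channels[[mus]] <- emg_channel(
      samples = x, fs = fs, fish = fish, muscle = mus,
      quiet_window = c(0.02, 0.45)
    )
    if (nrow(merged) > 0) {
      truth_all[[mus]] <- data.frame(
        fish = fish, behaviour = behaviour, muscle = mus,
        onset_s = merged$onset_s, offset_s = merged$offset_s,
        amp = merged$amp, merged = merged$merged
      )
    }
  }
  truth <- do.call(rbind, truth_all)
  rownames(truth) <- NULL
  list(channels = channels, truth_bursts = truth)
}

merge_scheduled_bursts <- function(onsets, offsets, amps) {
  n_merged <- 0L
  if (length(onsets) == 0) {
    out <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      amp = numeric(0), merged = logical(0))
    attr(out, "n_merged") <- 0L
    return(out)
  }
  on <- onsets[1]; off <- offsets[1]; am <- amps[1]; mg <- FALSE
  O <- c(); F <- c(); A <- c(); M <- c()
  for (i in seq_along(onsets)[-1]) {
    if (onsets[i] < off) {
      off <- max(off, offsets[i]); am <- max(am, amps[i])
      mg <- TRUE; n_merged <- n_merged + 1L
    } else {
      O <- c(O, on); F <- c(F, off); A <- c(A, am); M <- c(M, mg)
      on <- onsets[i]; off <- offsets[i]; am <- amps[i]; mg <- FALSE
    }
  }
  O <- c(O, on); F <- c(F, off); A <- c(A, am); M <- c(M, mg)
  out <- data.frame(onset_s = O, offset_s = F, amp = A, merged = M)
  attr(out, "n_merged") <- n_merged
  out
}

# Band-limited (40-4000 Hz) noise carrier of unit RMS with a trapezoidal
# amplitude envelope (5 ms rise/fall), scaled to `amp`.
burst_carrier <- function(len, fs, amp, rise_s = 0.005) {
  if (len < 8) return(numeric(len))
  raw <- rnorm(len)
  filt <- bandpass_filter(raw, fs)
  rms <- sqrt(mean(filt^2))
  if (rms > 0) filt <- filt / rms
  ramp_n <- min(round(rise_s * fs), floor(len / 2))
  env <- rep(1, len)
  if (ramp_n > 0) {
    env[seq_len(ramp_n)] <- seq(0, 1, length.out = ramp_n)
    env[(len - ramp_n + 1):len] <- seq(1, 0, length.out = ramp_n)
  }
  amp * filt * env
}

# ---- Kinematics generation --------------------------------------------

# Piecewise cycle phase: 0 at each cycle start, 1 at its end; extended with
# the first/last period outside the annotated cycles.
cycle_phase <- function(t, cycles) {
  phi <- numeric(length(t))
  T1 <- cycles$t_end[1] - cycles$t_start[1]
  Tn <- cycles$t_end[nrow(cycles)] - cycles$t_start[nrow(cycles)]
  phi[t < cycles$t_start[1]] <- (t[t < cycles$t_start[1]] - cycles$t_start[1]) / T1
  last_end <- cycles$t_end[nrow(cycles)]
  phi[t >= last_end] <- 1 + (t[t >= last_end] - last_end) / Tn
  for (i in seq_len(nrow(cycles))) {
    sel <- t >= cycles$t_start[i] & t < cycles$t_end[i]
    phi[sel] <- (t[sel] - cycles$t_start[i]) / (cycles$t_end[i] - cycles$t_start[i])
  }
  phi
}

# Analytic landmark positions (body lengths) at times t for one behaviour.
landmark_positions <- function(t, cycles, kp) {
  phi <- cycle_phase(t, cycles)
  osc <- function(amp, max_phase) amp * cos(2 * pi * (phi - max_phase))
  nose <- cbind(
    x = kp$speed_bl_s * t,
    y = kp$nose_lat_amp_bl * sin(2 * pi * phi),
    z = 0.05 + osc(kp$nose_elev_amp_bl, kp$nose_elev_max_phase)
  )
  base <- cbind(x = nose[, "x"] - 0.25, y = nose[, "y"], z = nose[, "z"] - 0.07)
  theta <- deg2rad(kp$add_centre_deg + osc(kp$add_amp_deg, kp$add_max_phase))
  tip <- cbind(
    x = base[, "x"] + 0.15 * cos(theta),
    y = base[, "y"] + 0.15 * sin(theta),
    z = kp$elev_centre_bl + osc(kp$elev_amp_bl, kp$elev_max_phase)
  )
  caudal <- cbind(x = nose[, "x"] - 0.8,
                  y = kp$caudal_amp_bl * sin(2 * pi * phi),
                  z = -0.03)
  list(nose_tip = nose, pect_base = base, pect_tip = tip, caudal_tip = caudal)
}

simulate_trajectories <- function(config, behaviour, cycles, total_dur) {
  kp <- config$kinematic_params[[behaviour]]
  fsv <- config$fs_video
  t <- seq(0, total_dur, by = 1 / fsv)
  pos <- landmark_positions(t, cycles, kp)
  traj <- do.call(rbind, lapply(names(pos), function(lm) {
    data.frame(frame = seq_along(t), time_s = t, landmark = lm,
               x = pos[[lm]][, "x"], y = pos[[lm]][, "y"],
               z = pos[[lm]][, "z"])
  }))
  rownames(traj) <- NULL

  pf <- config$propulsion_fraction[[behaviour]]
  truth <- do.call(rbind, lapply(seq_len(nrow(cycles)), function(i) {
    cyc <- cycles[i, ]
    Ti <- cyc$t_end - cyc$t_start
    phase_deg <- function(phase) phase_to_polar(phase %% 1, pf)
    # Fine quadrature of the analytic curves for path lengths
    tf <- seq(cyc$t_start, cyc$t_end, length.out = 4001)
    pf_pos <- landmark_positions(tf, cycles, kp)
    path2d <- function(m) sum(sqrt(diff(m[, "x"])^2 + diff(m[, "y"])^2))
    path3d <- function(m) sum(sqrt(diff(m[, "x"])^2 + diff(m[, "y"])^2 +
                                     diff(m[, "z"])^2))
    vmax <- 2 * pi * kp$add_amp_deg / Ti   # peak angular speed, deg/s
    # mean of the top q fraction (by magnitude) of a half-wave |sin|:
    # the top q of one sign class spans u in (pi/2 +/- q pi/2)
    top_frac <- function(q) sin(q * pi / 2) / (q * pi / 2)
    data.frame(
      cycle = cyc$cycle, behaviour = behaviour,
      t_start = cyc$t_start, t_mid = cyc$t_mid, t_end = cyc$t_end,
      speed_over_ground = path3d(pf_pos$nose_tip) / Ti,
      caudal_swing = path2d(pf_pos$caudal_tip),
      pect_swing = path2d(pf_pos$pect_tip),
      nose_swing = if (behaviour == "walking") path2d(pf_pos$nose_tip) else NA_real_,
      add_max = kp$add_centre_deg + kp$add_amp_deg,
      add_min = kp$add_centre_deg - kp$add_amp_deg,
      add_range = 2 * kp$add_amp_deg,
      add_max_deg = phase_deg(kp$add_max_phase),
      add_min_deg = phase_deg(kp$add_max_phase + 0.5),
      elev_max = kp$elev_centre_bl + kp$elev_amp_bl,
      elev_min = kp$elev_centre_bl - kp$elev_amp_bl,
      elev_range = 2 * kp$elev_amp_bl,
      elev_max_deg = phase_deg(kp$elev_max_phase),
      elev_min_deg = phase_deg(kp$elev_max_phase + 0.5),
      nose_elev_max_deg = if (kp$nose_elev_amp_bl > 0)
        phase_deg(kp$nose_elev_max_phase) else NA_real_,
      nose_elev_min_deg = if (kp$nose_elev_amp_bl > 0)
        phase_deg(kp$nose_elev_max_phase + 0.5) else NA_real_,
      add_vel_max = vmax * top_frac(0.05),
      add_vel_routine = vmax * top_frac(0.20),
      abd_vel_max = -vmax * top_frac(0.05),
      abd_vel_routine = -vmax * top_frac(0.20)
    )
  }))
  rownames(truth) <- NULL
  list(trajectories = traj, truth = truth)
}

# Map a cycle fraction to stroke-circle degrees: propulsion [0, pf) onto
# [0, 180), recovery [pf, 1) onto [180, 360).
phase_to_polar <- function(phase, pf) {
  ifelse(phase < pf, 180 * phase / pf, 180 + 180 * (phase - pf) / (1 - pf))
}
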
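#' Stroke-cycle kinematics from 3D landmark trajectories
#'
#' Per-cycle kinematic variables are computed from digitized trajectories
#' of four landmarks (nose tip, caudal fin tip, pectoral fin tip, pectoral
#' fin base) sampled at the video rate, with cycle boundaries supplied as
#' annotations (`t_start` = propulsion/stance start, `t_mid` = recovery/
#' swing start, `t_end` = next cycle start). All distances are in body
#' lengths; event times are mapped onto the stroke circle by
#' [to_polar_timing()].
#'
#' @name kinematics
NULL

# Rows of a single-landmark trajectory within [t0, t1] (closed), with
# basic coverage checks.
traj_window <- function(traj, t0, t1, min_rows = 2) {
  stopifnot(all(c("time_s", "x", "y", "z") %in% names(traj)))
  eps <- 1e-9
  if (t0 < min(traj$time_s) - eps || t1 > max(traj$time_s) + eps)
    stop(sprintf("window [%.4f, %.4f] outside trajectory [%.4f, %.4f]: check cycle annotation alignment",
                 t0, t1, min(traj$time_s), max(traj$time_s)))
  w <- traj[traj$time_s >= t0 - eps & traj$time_s <= t1 + eps, , drop = FALSE]
  if (nrow(w) < min_rows)
    stop("fewer than ", min_rows, " frames in window")
  if (any(!is.finite(w$x) | !is.finite(w$y) | !is.finite(w$z)))
    stop("missing frames inside the window; interpolate or drop the cycle")
  w[order(w$time_s), , drop = FALSE]
}

#' Speed over ground
#'
#' Path length of the nose-tip trajectory within the window divided by the
#' elapsed time between the first and last frame used. Uses the full 3D
#' path by default; set `use_z = FALSE` for the horizontal projection.
#'
#' @param nose Data frame with `time_s`, `x`, `y`, `z` (body lengths).
#' @param t0,t1 Window bounds in seconds (e.g. a cycle or a whole trial).
#' @param use_z Include the vertical coordinate in the path (default TRUE).
#' @return Speed in body lengths per second.
#' @export
speed_over_ground <- function(nose, t0, t1, use_z = TRUE) {
  w <- traj_window(nose, t0, t1)
  dz <- if (use_z) diff(w$z) else 0
  len <- sum(sqrt(diff(w$x)^2 + diff(w$y)^2 + dz^2))
  len / (w$time_s[nrow(w)] - w$time_s[1])
}

#' Swing distance of a landmark over one cycle
#'
#' Total distance travelled in the x-y plane (vertical motion excluded)
#' between `t_start` and `t_end` of the cycle.
#'
#' @param tip Data frame with `time_s`, `x`, `y`, `z`.
#' @param cycle One-row data frame or list with `t_start` and `t_end`.
#' @return Path length in body lengths.
#' @export
swing_distance <- function(tip, cycle) {
  w <- traj_window(tip, cycle$t_start, cycle$t_end)
  sum(sqrt(diff(w$x)^2 + diff(w$y)^2))
}

#' Elevation extremes within one cycle
#'
#' Maximum, minimum and range of the vertical coordinate, with the timing
#' of each extreme on the stroke circle. Larger values are more dorsal.
#' Ties are resolved to the first occurrence (with a warning).
#'
#' @param tip Data frame with `time_s`, `x`, `y`, `z`.
#' @param cycle List with `t_start`, `t_mid`, `t_end`.
#' @return List: `max`, `min`, `range`, `max_deg`, `min_deg`.
#' @export
elevation_stats <- function(tip, cycle) {
  w <- traj_window(tip, cycle$t_start, cycle$t_end)
  series_extremes(w$z, w$time_s, cycle)
}

series_extremes <- function(v, time_s, cycle) {
  imax <- which(v == max(v)); imin <- which(v == min(v))
  if (length(imax) > 1 || length(imin) > 1)
    warning("tied extreme values; first occurrence reported")
  i1 <- imax[1]; i2 <- imin[1]
  clamp <- function(t) min(t, cycle$t_end - 1e-12)
  list(max = v[i1], min = v[i2], range = v[i1] - v[i2],
       max_deg = to_polar_timing(clamp(time_s[i1]), cycle),
       min_deg = to_polar_timing(clamp(time_s[i2]), cycle))
}

#' Pectoral fin adduction angle series
#'
#' Oriented planar angle at the fin-base vertex between the nose tip and
#' the fin tip in the x-y plane, unwrapped to a continuous scale so that
#' sweeps past the body axis give values above 180 degrees (more adducted).
#' The first frame is placed in [0, 360) and subsequent frames follow
#' continuously.
#'
#' @param nose,base,tip Data frames with `time_s`, `x`, `y` on the same
#'   frame grid.
#' @return Data frame with `time_s` and `angle_deg`.
#' @export
adduction_angle <- function(nose, base, tip) {
  stopifnot(nrow(nose) == nrow(base), nrow(base) == nrow(tip))
  if (max(abs(nose$time_s - base$time_s), abs(tip$time_s - base$time_s)) > 1e-9)
    stop("landmarks must share frames")
  v1x <- nose$x - base$x; v1y <- nose$y - base$y
  v2x <- tip$x - base$x; v2y <- tip$y - base$y
  n1 <- sqrt(v1x^2 + v1y^2); n2 <- sqrt(v2x^2 + v2y^2)
  bad <- which(n1 < 1e-12 | n2 < 1e-12)
  if (length(bad) > 0)
    stop("undefined angle: coincident landmarks at frame ", bad[1])
  raw <- rad2deg(atan2(v1x * v2y - v1y * v2x, v1x * v2x + v1y * v2y)) %% 360
  d <- diff(raw)
  d <- (d + 180) %% 360 - 180   # shortest signed step between frames
  data.frame(time_s = nose$time_s, angle_deg = raw[1] + c(0, cumsum(d)))
}

#' Angular velocity summaries for one cycle
#'
#' Central-difference angular velocity of the adduction angle. Negative
#' samples are pooled as abduction, positive as adduction; within each sign
#' class the mean of the top 5% (by magnitude) represents maximum velocity
#' and the mean of the top 20% represents routine velocity, signed so
#' abduction summaries are negative. An empty sign class gives `NA`, not
#' zero.
#'
#' @param angle Data frame from [adduction_angle()] (`time_s`,
#'   `angle_deg`).
#' @param cycle List with `t_start`, `t_end`.
#' @param min_samples Minimum velocity samples required (default 20).
#' @return List: `abd_vel_max`, `abd_vel_routine`, `add_vel_max`,
#'   `add_vel_routine` (deg/s).
#' @export
angular_velocity_summary <- function(angle, cycle, min_samples = 20) {
  w <- angle[angle$time_s >= cycle$t_start - 1e-9 &
               angle$time_s <= cycle$t_end + 1e-9, , drop = FALSE]
  n <- nrow(w)
  if (n < min_samples + 2)
    stop("need at least ", min_samples, " velocity samples in the cycle")
  i <- 2:(n - 1)
  v <- (w$angle_deg[i + 1] - w$angle_deg[i - 1]) /
    (w$time_s[i + 1] - w$time_s[i - 1])
  top_mean <- function(x, q) {
    if (length(x) == 0) return(NA_real_)
    k <- max(1L, ceiling(q * length(x)))
    mean(sort(x, decreasing = TRUE)[seq_len(k)])
  }
  add <- v[v > 0]; abd <- -v[v < 0]   # magnitudes
  list(abd_vel_max = -top_mean(abd, 0.05),
       abd_vel_routine = -top_mean(abd, 0.20),
       add_vel_max = top_mean(add, 0.05),
       add_vel_routine = top_mean(add, 0.20))
}

#' Map an event time onto the stroke circle
#'
#' Phase-normalized polar mapping: the propulsive phase
#' (`t_start` to `t_mid`) maps linearly onto \[0, 180) degrees and the
#' recovery phase (`t_mid` to `t_end`) onto \[180, 360), so the recovery
#' start is pinned at 180 degrees regardless of the propulsion fraction.
#' `mapping = "time"` instead maps raw time fraction onto \[0, 360).
#'
#' @param t Event time(s) in seconds, each in `[t_start, t_end)`.
#' @param cycle List with `t_start`, `t_mid`, `t_end`.
#' @param mapping `"phase"` (default) or `"time"`.
#' @return Degrees in \[0, 360).
#' @export
to_polar_timing <- function(t, cycle, mapping = c("phase", "time")) {
  mapping <- match.arg(mapping)
  if (any(t < cycle$t_start - 1e-9 | t >= cycle$t_end))
    stop("event time outside cycle [", cycle$t_start, ", ", cycle$t_end, ")")
  if (mapping == "time") {
    return(360 * (t - cycle$t_start) / (cycle$t_end - cycle$t_start))
  }
  ifelse(t < cycle$t_mid,
         180 * (t - cycle$t_start) / (cycle$t_mid - cycle$t_start),
         180 + 180 * (t - cycle$t_mid) / (cycle$t_end - cycle$t_mid))
}

#' Per-cycle kinematic variable table
#'
#' Runs every per-cycle variable over a tidy trajectory table and cycle
#' annotations: speed over ground, caudal/pectoral (and, for walking,
#' nose) swing distances, fin elevation extremes with polar timings,
#' adduction-angle extremes with polar timings, angular velocity summaries,
#' and nose elevation timings for walking.
#'
#' @param trajectories Data frame with `time_s`, `landmark`, `x`, `y`, `z`
#'   (landmarks `nose_tip`, `caudal_tip`, `pect_tip`, `pect_base`).
#' @param cycles Data frame with `t_start`, `t_mid`, `t_end`, `behaviour`
#'   (and optionally `cycle`, `fish`).
#' @param speed_use_z Passed to [speed_over_ground()].
#' @return Data frame, one row per cycle.
#' @export
cycle_kinematics <- function(trajectories, cycles, speed_use_z = TRUE) {
  lm_tab <- split(trajectories, trajectories$landmark)
  for (lm in c("nose_tip", "caudal_tip", "pect_tip", "pect_base"))
    if (is.null(lm_tab[[lm]])) stop("missing landmark '", lm, "'")
  out <- lapply(seq_len(nrow(cycles)), function(i) {
    cyc <- as.list(cycles[i, ])
    nose <- traj_window(lm_tab$nose_tip, cyc$t_start, cyc$t_end)
    base <- traj_window(lm_tab$pect_base, cyc$t_start, cyc$t_end)
    tip <- traj_window(lm_tab$pect_tip, cyc$t_start, cyc$t_end)
    ang <- adduction_angle(nose, base, tip)
    ang_ext <- series_extremes(ang$angle_deg, ang$time_s, cyc)
    vel <- angular_velocity_summary(ang, cyc)
    elev <- elevation_stats(lm_tab$pect_tip, cyc)
    walking <- identical(cyc$behaviour, "walking")
    nose_elev <- if (walking) elevation_stats(lm_tab$nose_tip, cyc) else NULL
    data.frame(
      cycle = if (!is.null(cyc$cycle)) cyc$cycle else i,
      fish = if (!is.null(cyc$fish)) cyc$fish else NA,
      behaviour = cyc$behaviour,
      t_start = cyc$t_start, t_mid = cyc$t_mid, t_end = cyc$t_end,
      speed_over_ground = speed_over_ground(lm_tab$nose_tip, cyc$t_start,
                                            cyc$t_end, use_z = speed_use_z),
      caudal_swing = swing_distance(lm_tab$caudal_tip, cyc),
      pect_swing = swing_distance(lm_tab$pect_tip, cyc),
      nose_swing = if (walking) swing_distance(lm_tab$nose_tip, cyc) else NA_real_,
      elev_max = elev$max, elev_min = elev$min, elev_range = elev$range,
      elev_max_deg = elev$max_deg, elev_min_deg = elev$min_deg,
      add_max = ang_ext$max, add_min = ang_ext$min, add_range = ang_ext$range,
      add_max_deg = ang_ext$max_deg, add_min_deg = ang_ext$min_deg,
      nose_elev_max_deg = if (walking) nose_elev$max_deg else NA_real_,
      nose_elev_min_deg = if (walking) nose_elev$min_deg else NA_real_,
      abd_vel_max = vel$abd_vel_max, abd_vel_routine = vel$abd_vel_routine,
      add_vel_max = vel$add_vel_max, add_vel_routine = vel$add_vel_routine
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
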
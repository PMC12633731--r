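cycle1 <- list(t_start = 1, t_mid = 1.4, t_end = 2)  # 40% propulsion

test_that("polar mapping pins the phase boundaries and is monotone", {
  expect_equal(to_polar_timing(1, cycle1), 0)
  expect_equal(to_polar_timing(1.4, cycle1), 180)
  expect_equal(to_polar_timing(1.7, cycle1), 270)  # halfway through recovery
  expect_equal(to_polar_timing(1.2, cycle1), 90)
  # raw-time mapping alternative
  expect_equal(to_polar_timing(1.4, cycle1, mapping = "time"), 144)
  expect_error(to_polar_timing(2.0, cycle1), "outside")
  expect_error(to_polar_timing(0.99, cycle1), "outside")
  # monotone and surjective onto [0, 360)
  for (s in 1:5) {
    set.seed(s)
    t0 <- runif(1); pf <- runif(1, 0.2, 0.8); dur <- runif(1, 0.2, 1)
    cyc <- list(t_start = t0, t_mid = t0 + pf * dur, t_end = t0 + dur)
    tt <- sort(runif(200, t0, t0 + dur - 1e-9))
    deg <- to_polar_timing(tt, cyc)
    expect_true(all(diff(deg) >= 0))
    expect_true(all(deg >= 0 & deg < 360))
    expect_lt(abs(to_polar_timing(t0 + dur - 1e-9, cyc) - 360), 1e-4)
  }
})

test_that("speed over ground matches path-length oracles", {
  tt <- seq(0, 2, by = 1 / 500)
  still <- data.frame(time_s = tt, x = 1, y = 2, z = 3)
  expect_equal(speed_over_ground(still, 0, 2), 0)
  straight <- data.frame(time_s = tt, x = tt / 2, y = 0, z = 0)
  expect_equal(speed_over_ground(straight, 0, 2), 0.5)
  set.seed(1)
  zig <- data.frame(time_s = tt, x = cumsum(rnorm(length(tt), 0.001, 0.002)),
                    y = 0.05 * sin(8 * pi * tt), z = 0.01 * cos(6 * pi * tt))
  w <- zig[zig$time_s >= 0.25 & zig$time_s <= 1.75, ]
  expect_equal(speed_over_ground(zig, 0.25, 1.75),
               oracle_path3d(w$x, w$y, w$z) / (max(w$time_s) - min(w$time_s)),
               tolerance = 1e-12)
  # horizontal-projection option
  expect_equal(speed_over_ground(zig, 0.25, 1.75, use_z = FALSE),
               oracle_path2d(w$x, w$y) / (max(w$time_s) - min(w$time_s)),
               tolerance = 1e-12)
  expect_error(speed_over_ground(zig, -1, 1), "outside")
})

test_that("swing distance is a 2D path length, invariant to translation and z", {
  tt <- seq(0, 1, by = 1 / 500)
  cyc <- list(t_start = 0, t_mid = 0.5, t_end = 1)
  none <- data.frame(time_s = tt, x = 0.3, y = -0.1, z = sin(2 * pi * tt))
  expect_equal(swing_distance(none, cyc), 0)  # pure vertical motion excluded
  sine <- data.frame(time_s = tt, x = tt, y = 0.2 * sin(2 * pi * tt), z = 0)
  w <- sine[sine$time_s <= 1, ]
  expect_equal(swing_distance(sine, cyc), oracle_path2d(w$x, w$y),
               tolerance = 1e-12)
  shifted <- transform(sine, x = x + 5, y = y - 3, z = z + 100)
  expect_equal(swing_distance(shifted, cyc), swing_distance(sine, cyc),
               tolerance = 1e-12)
})

test_that("elevation extremes and their polar timings are recovered", {
  tt <- seq(0, 1, by = 1 / 500)
  cyc <- list(t_start = 0, t_mid = 0.4, t_end = 1)
  flat <- data.frame(time_s = tt, x = 0, y = 0, z = 1)
  expect_warning(st <- elevation_stats(flat, cyc), "tie")
  expect_equal(st$range, 0)
  # single peak at the midpoint of propulsion -> max timing 90 degrees
  z <- -((tt - 0.2))^2
  peak <- data.frame(time_s = tt, x = 0, y = 0, z = z)
  st <- elevation_stats(peak, cyc)
  expect_equal(st$max_deg, 90, tolerance = 1.5)
  # noisy series: extremes match argmax/argmin oracle
  set.seed(2)
  zn <- sin(2 * pi * tt) + rnorm(length(tt), 0, 0.1)
  noisy <- data.frame(time_s = tt, x = 0, y = 0, z = zn)
  st <- elevation_stats(noisy, cyc)
  expect_equal(st$max, max(zn[tt <= 1]))
  expect_equal(st$min, min(zn[tt <= 1]))
  expect_equal(st$range, max(zn) - min(zn))
})

test_that("adduction angle is the oriented planar angle, unwrapped past 180", {
  tt <- c(0, 0.002)
  mk <- function(nx, ny, bx, by, tx, ty)
    list(nose = data.frame(time_s = tt, x = nx, y = ny),
         base = data.frame(time_s = tt, x = bx, y = by),
         tip = data.frame(time_s = tt, x = tx, y = ty))
  g <- mk(0, 1, 0, 0, 0, -1)   # collinear through the base
  expect_equal(adduction_angle(g$nose, g$base, g$tip)$angle_deg,
               c(180, 180))
  g <- mk(0, 1, 0, 0, 1, 0)
  a <- adduction_angle(g$nose, g$base, g$tip)$angle_deg
  expect_true(all(abs(a - 90) < 1e-9 | abs(a - 270) < 1e-9))
  # sweep 30 degrees past the body axis -> continuous max 210
  tt2 <- seq(0, 1, by = 1 / 500)
  theta <- 180 + 30 * sin(2 * pi * tt2)
  nose <- data.frame(time_s = tt2, x = 1, y = 0)
  base <- data.frame(time_s = tt2, x = 0, y = 0)
  tip <- data.frame(time_s = tt2, x = cos(theta * pi / 180),
                    y = sin(theta * pi / 180))
  ang <- adduction_angle(nose, base, tip)
  expect_equal(max(ang$angle_deg), 210, tolerance = 0.01)
  expect_equal(min(ang$angle_deg), 150, tolerance = 0.01)
  expect_equal(ang$angle_deg, theta, tolerance = 1e-9)
  # invariant to uniform scaling
  sc <- adduction_angle(transform(nose, x = 3 * x, y = 3 * y),
                        transform(base, x = 3 * x, y = 3 * y),
                        transform(tip, x = 3 * x, y = 3 * y))
  expect_equal(sc$angle_deg, ang$angle_deg, tolerance = 1e-9)
  expect_error(adduction_angle(nose, base,
                               data.frame(time_s = tt2, x = 0, y = 0)),
               "coincident")
})

test_that("angular velocity summaries match a sort-and-average oracle", {
  tt <- seq(0, 1, by = 1 / 500)
  cyc <- list(t_start = 0, t_mid = 0.5, t_end = 1)
  const <- data.frame(time_s = tt, angle_deg = 100)
  v <- angular_velocity_summary(const, cyc)
  expect_true(all(is.na(unlist(v))))
  ramp <- data.frame(time_s = tt, angle_deg = 100 * tt)
  v <- angular_velocity_summary(ramp, cyc)
  expect_equal(v$add_vel_max, 100, tolerance = 1e-9)
  expect_equal(v$add_vel_routine, 100, tolerance = 1e-9)
  expect_true(is.na(v$abd_vel_max) && is.na(v$abd_vel_routine))
  # sinusoid vs brute force on the same central differences
  ang <- data.frame(time_s = tt, angle_deg = 180 + 30 * sin(2 * pi * tt))
  v <- angular_velocity_summary(ang, cyc)
  n <- nrow(ang)
  i <- 2:(n - 1)
  vel <- (ang$angle_deg[i + 1] - ang$angle_deg[i - 1]) /
    (ang$time_s[i + 1] - ang$time_s[i - 1])
  topmean <- function(x, q) mean(sort(x, decreasing = TRUE)[
    seq_len(max(1, ceiling(q * length(x))))])
  expect_equal(v$add_vel_max, topmean(vel[vel > 0], 0.05), tolerance = 1e-12)
  expect_equal(v$add_vel_routine, topmean(vel[vel > 0], 0.20), tolerance = 1e-12)
  expect_equal(v$abd_vel_max, -topmean(-vel[vel < 0], 0.05), tolerance = 1e-12)
  expect_equal(v$abd_vel_routine, -topmean(-vel[vel < 0], 0.20),
               tolerance = 1e-12)
  expect_lte(v$abd_vel_max, 0); expect_gte(v$add_vel_max, 0)
  expect_error(angular_velocity_summary(ang[1:10, ],
                                        list(t_start = 0, t_end = 0.02)),
               "at least")
})

test_that("per-cycle table matches the generator's closed-form truth", {
  cfg <- tiny_config()
  for (b in c("swimming", "walking")) {
    kin <- suppressWarnings(generate_kinematics(cfg, 1, b))
    k <- suppressWarnings(cycle_kinematics(kin$trajectories, kin$cycles))
    tru <- kin$truth
    frame_s <- 1 / cfg$fs_video
    # one-frame discretization bounds
    expect_lt(max(abs(k$add_max - tru$add_max)), 0.05)
    expect_lt(max(abs(k$add_range - tru$add_range)), 0.1)
    expect_lt(max(abs(k$elev_range - tru$elev_range)), 1e-4)
    deg_tol <- 360 * frame_s / min(tru$t_end - tru$t_start) + 0.5
    expect_lt(max(abs(k$add_max_deg - tru$add_max_deg)), deg_tol)
    expect_lt(max(abs(k$elev_max_deg - tru$elev_max_deg)), deg_tol)
    expect_lt(max(abs(k$speed_over_ground / tru$speed_over_ground - 1)), 0.01)
    expect_lt(max(abs(k$pect_swing / tru$pect_swing - 1)), 0.02)
    expect_lt(max(abs(k$caudal_swing / tru$caudal_swing - 1)), 0.02)
    expect_lt(max(abs(k$add_vel_max / tru$add_vel_max - 1)), 0.02)
    expect_lt(max(abs(k$add_vel_routine / tru$add_vel_routine - 1)), 0.02)
    if (b == "walking") {
      expect_true(all(is.finite(k$nose_swing)))
      expect_lt(max(abs(k$nose_elev_max_deg - tru$nose_elev_max_deg)), deg_tol)
    } else {
      expect_true(all(is.na(k$nose_swing)))
    }
  }
})

test_that("zero oscillation amplitude gives zero ranges and pure translation speed", {
  cfg <- tiny_config()
  kp <- cfg$kinematic_params$swimming
  kp$add_amp_deg <- 0; kp$elev_amp_bl <- 0; kp$caudal_amp_bl <- 0
  cfg$kinematic_params$swimming <- kp
  kin <- generate_kinematics(cfg, 1, "swimming")
  k <- suppressWarnings(cycle_kinematics(kin$trajectories, kin$cycles))
  expect_true(all(abs(k$elev_range) < 1e-12))
  expect_true(all(abs(k$add_range) < 1e-9))
  expect_equal(k$speed_over_ground, rep(kp$speed_bl_s, nrow(k)),
               tolerance = 1e-9)
})
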
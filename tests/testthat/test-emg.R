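test_that("centering subtracts the quiet-window baseline", {
  fs <- 10000
  const <- emg_channel(rep(0.7, fs), fs, quiet_window = c(0.1, 0.5))
  expect_equal(center_signal(const)$samples, rep(0, fs))
  set.seed(1)
  x <- rnorm(fs)
  ch0 <- emg_channel(x, fs, quiet_window = c(0.1, 0.5))
  ch1 <- emg_channel(x + 0.3, fs, quiet_window = c(0.1, 0.5))
  expect_equal(center_signal(ch1)$samples, center_signal(ch0)$samples,
               tolerance = 1e-12)
  qmean <- mean(center_signal(ch0)$samples[1001:5000])
  expect_lt(abs(qmean), 1e-12)
  short <- emg_channel(x, fs, quiet_window = c(0.1, 0.14))
  expect_error(center_signal(short), "50 ms")
  expect_error(emg_channel(x, fs, quiet_window = c(0.5, 2)), "inside")
})

test_that("bandpass keeps the passband and rejects out-of-band tones", {
  fs <- 10000
  tt <- seq(0, 2, by = 1 / fs)
  amp_out <- function(f) {
    y <- bandpass_filter(sin(2 * pi * f * tt), fs)
    sqrt(mean(y[3000:17000]^2)) * sqrt(2)
  }
  dc <- bandpass_filter(rep(1, 3 * fs), fs)
  expect_lt(max(abs(dc[5000:25000])), 0.01)  # DC, steady state
  a500 <- amp_out(500)
  expect_gte(a500, 0.89); expect_lte(a500, 1.001)
  expect_lt(amp_out(10), 0.1)
  expect_lt(amp_out(4500), 0.1)
  expect_error(bandpass_filter(tt, fs = 8000), "twice")
})

test_that("periodized sym4 DWT matches the reference transform and inverts", {
  x <- c(0.304717, -1.039984, 0.750451, 0.940565, -1.951035, -1.302180,
         0.127840, -0.316243, -0.016801, -0.853044, 0.879398, 0.777792,
         0.066031, 1.127241, 0.467509, -0.859292)
  # frozen oracle values from an independent reference implementation
  cA <- c(-0.1360379681, 0.1091867270, -1.6897755726, -0.0817065066,
          -0.2932712120, 0.9257679094, 1.0449510051, -0.5134139139)
  cD <- c(-0.9283583350, -0.9476796326, 1.7665473391, -0.9932691918,
          -0.2201789269, -0.8988837211, 0.8078201680, -0.1085789119)
  w <- dwt_sym4(x, 1)
  expect_equal(w$a, cA, tolerance = 1e-9)
  expect_equal(w$d[[1]], cD, tolerance = 1e-9)
  set.seed(3)
  for (n in c(64, 256, 1024)) {
    y <- rnorm(n)
    w <- dwt_sym4(y, 4)
    expect_equal(idwt_sym4(w), y, tolerance = 1e-10)
    # orthonormality: energy preserved
    expect_equal(sum(w$a^2) + sum(unlist(w$d)^2), sum(y^2),
                 tolerance = 1e-10)
  }
})

test_that("empirical-Bayes denoising shrinks noise but keeps burst energy", {
  expect_equal(denoise_emg(numeric(64)), numeric(64))
  set.seed(11)
  noise <- rnorm(2^16)
  expect_lt(sd(denoise_emg(noise)), 0.5)
  # burst at SNR 10 retains >= 90% of its energy
  fs <- 10000; n <- 2^15
  idx <- 10000:15000
  car <- bandpass_filter(rnorm(length(idx)), fs)
  car <- car / sqrt(mean(car^2))
  y <- rnorm(n, 0, 0.1)
  y[idx] <- y[idx] + car
  dy <- denoise_emg(y)
  expect_gte(sum(dy[idx]^2) / sum(y[idx]^2), 0.9)
  expect_error(denoise_emg(c(1, NA, 3, rep(0, 61))), "finite")
  expect_error(denoise_emg(rnorm(8)), "16")
})

test_that("moving RMS envelope matches the windowed oracle", {
  expect_equal(rms_envelope(rep(2, 1000), 400), rep(2, 1000))
  fs <- 10000
  tt <- seq(0, 1, by = 1 / fs)
  s <- 3 * sin(2 * pi * 500 * tt)
  env <- rms_envelope(s, 400)   # window of 20 periods
  expect_equal(mean(env[2000:8000]), 3 / sqrt(2), tolerance = 1e-3)
  set.seed(4)
  x <- rnorm(300)
  for (w in c(1, 7, 50)) expect_equal(rms_envelope(x, w), oracle_rms(x, w),
                                      tolerance = 1e-12)
  expect_error(rms_envelope(x, 301))
})

test_that("burst detection thresholds at 25% of the envelope mean", {
  fs <- 1000
  env <- numeric(1000)
  env[101:200] <- 1   # plateau on [0.10, 0.20) s
  b <- detect_bursts(env, fs)
  expect_equal(nrow(b), 1)
  expect_equal(b$onset_s, 0.100, tolerance = 2 / fs)
  expect_equal(b$offset_s, 0.200, tolerance = 2 / fs)
  # constant envelope: always above 0.25 of its mean -> one full-record burst
  b <- detect_bursts(rep(3, 500), fs)
  expect_equal(nrow(b), 1)
  expect_equal(b$onset_s, 0); expect_equal(b$offset_s, 0.5)
  expect_equal(nrow(detect_bursts(numeric(100), fs)), 0)
})

test_that("rate filter merges <10 ms gaps then drops <10 ms bursts, idempotently", {
  b <- data.frame(onset_s = c(0.1, 0.205), offset_s = c(0.2, 0.3))
  f <- rate_filter(b)
  expect_equal(nrow(f), 1)
  expect_equal(f$onset_s, 0.1); expect_equal(f$offset_s, 0.3)
  expect_equal(nrow(rate_filter(data.frame(onset_s = 0.5, offset_s = 0.504))), 0)
  # random burst trains vs the independent oracle
  set.seed(5)
  for (r in 1:20) {
    n <- sample(1:15, 1)
    on <- sort(runif(n, 0, 2))
    dur <- runif(n, 0.002, 0.08)
    off <- pmin(on + dur, c(on[-1] - 1e-4, Inf))  # keep inputs disjoint
    b <- data.frame(onset_s = on, offset_s = off)
    got <- rate_filter(b)
    want <- oracle_rate_filter(b)
    expect_equal(got, want, tolerance = 1e-12)
    expect_equal(rate_filter(got), got, tolerance = 1e-12)  # idempotent
  }
})

test_that("burst metrics match the trapezoid oracle and keep exact identities", {
  fs <- 10000
  cyc <- list(t_start = 0.1, t_mid = 0.35, t_end = 0.6)
  # constant-amplitude burst equal to the channel max, 10% of the cycle
  x <- numeric(fs)
  bst <- data.frame(onset_s = 0.15, offset_s = 0.20)
  i <- (bst$onset_s * fs + 1):(bst$offset_s * fs + 1)
  x[i] <- 0.8
  m <- burst_metrics(x, fs, bst, cyc, norm = list(max_amp = 0.8))
  full <- m[m$scope == "full_cycle", ]
  expect_equal(full$duty_factor_pct, 10, tolerance = 1e-9)
  expect_equal(full$ria_pct, 100, tolerance = 1e-9)
  expect_equal(full$amp_pct, 100, tolerance = 1e-12)
  expect_equal(full$activation_duration_s * 100 / (cyc$t_end - cyc$t_start),
               full$duty_factor_pct, tolerance = 1e-12)
  # burst exactly spanning propulsion
  bp <- data.frame(onset_s = cyc$t_start, offset_s = cyc$t_mid)
  m <- burst_metrics(x + 0.1, fs, bp, cyc, norm = list(max_amp = 1))
  expect_equal(m$duty_factor_pct[m$scope == "propulsion"], 100)
  expect_equal(m$duty_factor_pct[m$scope == "recovery"], 0)
  expect_equal(m$n_bursts[m$scope == "recovery"], 0)
  expect_true(is.na(m$amp_pct[m$scope == "recovery"]))
  # multi-burst cycle vs brute-force integration oracle
  set.seed(6)
  y <- rnorm(fs, 0, 0.2)
  bs <- data.frame(onset_s = c(0.12, 0.30, 0.45), offset_s = c(0.2, 0.42, 0.55))
  norm <- list(max_amp = 1.5)
  m <- burst_metrics(y, fs, bs, cyc, norm)
  for (sc in list(c("full_cycle", 0.1, 0.6), c("propulsion", 0.1, 0.35),
                  c("recovery", 0.35, 0.6))) {
    lim <- as.numeric(sc[2:3])
    con <- pmax(bs$onset_s, lim[1]); coff <- pmin(bs$offset_s, lim[2])
    sel <- which(coff > con)
    act <- sum(coff[sel] - con[sel])
    ria <- sum(sapply(sel, function(k) oracle_rect_integral(y, fs, con[k], coff[k])))
    pooled <- unlist(lapply(sel, function(k) {
      i0 <- floor(con[k] * fs + 1e-9) + 1; i1 <- floor(coff[k] * fs + 1e-9) + 1
      abs(y[i0:i1])
    }))
    top5 <- mean(sort(pooled, decreasing = TRUE)[
      seq_len(ceiling(0.05 * length(pooled)))])
    row <- m[m$scope == sc[1], ]
    expect_equal(row$activation_duration_s, act, tolerance = 1e-12)
    expect_equal(row$ria_pct, 100 * ria / (norm$max_amp * act),
                 tolerance = 1e-8)
    expect_equal(row$amp_pct, 100 * top5 / norm$max_amp, tolerance = 1e-8)
  }
  # phases partition the cycle activation exactly
  expect_equal(m$activation_duration_s[m$scope == "propulsion"] +
                 m$activation_duration_s[m$scope == "recovery"],
               m$activation_duration_s[m$scope == "full_cycle"],
               tolerance = 1e-12)
})

test_that("channel normalization takes the channel-wide maximum", {
  expect_equal(channel_normalization(
    data.frame(amp_top5 = c(1, 3, 2)))$max_amp, 3)
  expect_equal(channel_normalization(c(0.2, 0.9))$max_amp, 0.9)
  expect_error(channel_normalization(data.frame(amp_top5 = numeric(0))),
               "undefined")
})

test_that("detection recovers scheduled bursts on simulated channels", {
  cfg <- gait_sim_config(n_fish = 1, cycles_per_fish = 12, noise_sd = 0.2,
                         seed = 19)
  tr <- simulate_trial(cfg, 1, "swimming")
  p <- process_channel(tr$channels$Abd)
  truth <- tr$truth$bursts[tr$truth$bursts$muscle == "Abd", ]
  m <- match_bursts(p$bursts, truth)
  expect_gte(m$recall, 0.95)
  expect_gte(m$precision, 0.9)
  expect_gte(m$boundary_ok, 0.9)
})
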
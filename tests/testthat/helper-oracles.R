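# Small configs and independent brute-force oracles used across tests.

tiny_config <- function(...) {
  gait_sim_config(n_fish = 2, cycles_per_fish = 3, seed = 42L, ...)
}

# One noiseless, jitter-free burst per cycle: the signal is exactly zero
# outside scheduled bursts.
noiseless_config <- function(onset = 0.4, offset = 0.8, muscle = "Abd") {
  gait_sim_config(
    n_fish = 1, cycles_per_fish = 1,
    cycle_duration = list(swimming = c(mean = 0.25, sd = 0),
                          walking = c(mean = 0.6, sd = 0)),
    burst_schedule = data.frame(muscle = muscle, behaviour = "swimming",
                                onset_phase = onset, offset_phase = offset,
                                amp = 1),
    timing_kappa = 0, noise_sd = 0, artifact_rate = 0, seed = 7L
  )
}

# Polyline length oracles.
oracle_path2d <- function(x, y) {
  s <- 0
  for (i in 2:length(x)) s <- s + sqrt((x[i] - x[i - 1])^2 + (y[i] - y[i - 1])^2)
  s
}
oracle_path3d <- function(x, y, z) {
  s <- 0
  for (i in 2:length(x))
    s <- s + sqrt((x[i] - x[i - 1])^2 + (y[i] - y[i - 1])^2 + (z[i] - z[i - 1])^2)
  s
}

# Windowed RMS by explicit loops.
oracle_rms <- function(x, window) {
  n <- length(x)
  half_lo <- floor((window - 1) / 2)
  half_hi <- window - 1 - half_lo
  sapply(seq_len(n), function(i) {
    lo <- max(1, i - half_lo); hi <- min(n, i + half_hi)
    sqrt(mean(x[lo:hi]^2))
  })
}

# Independent merge-then-drop rate rule: repeatedly merge the closest
# offending gap until stable, then drop short bursts.
oracle_rate_filter <- function(b, min_gap = 0.010, min_dur = 0.010) {
  repeat {
    if (nrow(b) < 2) break
    gaps <- b$onset_s[-1] - b$offset_s[-nrow(b)]
    i <- which(gaps < min_gap)
    if (length(i) == 0) break
    i <- i[1]
    b$offset_s[i] <- max(b$offset_s[i], b$offset_s[i + 1])
    b <- b[-(i + 1), , drop = FALSE]
  }
  b <- b[b$offset_s - b$onset_s >= min_dur, , drop = FALSE]
  rownames(b) <- NULL
  b
}

# Trapezoid integral of |x| over [t0, t1] by explicit loop over the same
# sample grid the implementation uses.
oracle_rect_integral <- function(x, fs, t0, t1) {
  i0 <- max(1, floor(t0 * fs + 1e-9) + 1)
  i1 <- min(length(x), floor(t1 * fs + 1e-9) + 1)
  r <- abs(x[i0:i1])
  s <- 0
  for (k in 2:length(r)) s <- s + (r[k] + r[k - 1]) / 2
  s / fs
}

# Greedy overlap matching of detected vs true bursts; returns recall,
# precision and the fraction with both boundaries within tol seconds.
match_bursts <- function(det, truth, tol = 0.020) {
  used <- rep(FALSE, nrow(det))
  matched <- 0; within <- 0
  for (i in seq_len(nrow(truth))) {
    ov <- pmin(det$offset_s, truth$offset_s[i]) -
      pmax(det$onset_s, truth$onset_s[i])
    ov[used] <- -Inf
    j <- which.max(ov)
    if (length(j) == 1 && ov[j] > 0) {
      used[j] <- TRUE
      matched <- matched + 1
      if (abs(det$onset_s[j] - truth$onset_s[i]) <= tol &&
          abs(det$offset_s[j] - truth$offset_s[i]) <= tol)
        within <- within + 1
    }
  }
  list(recall = matched / nrow(truth),
       precision = matched / nrow(det),
       boundary_ok = within / nrow(truth))
}

# Re-derive the expected decision-tree routing from the recorded sub-test
# outcomes and check the tree complied.
conforms_to_rule <- function(tr, alpha = 0.05, r_cutoff = 0.45) {
  sa <- tr$sample_a; sb <- tr$sample_b
  if (is.null(sb)) return(is.null(tr$comparison))
  if (sa$is_uniform || sb$is_uniform) return(is.null(tr$comparison))
  want <- if (sa$is_vonmises && sb$is_vonmises &&
              sa$summary$R_bar > r_cutoff && sb$summary$R_bar > r_cutoff)
    "watson_williams" else "watson_u2"
  ok_unif <- function(s) {
    expected <- if (isTRUE(s$kuiper$degenerate)) "degenerate"
    else if (s$is_vonmises) "rayleigh" else "hermans_rasson"
    identical(s$uniformity$test, expected)
  }
  !is.null(tr$comparison) && identical(tr$comparison$test, want) &&
    ok_unif(sa) && ok_unif(sb)
}
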
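#' End-to-end pipeline on synthetic data
#'
#' Simulates the full study (every fish x behaviour trial), runs the
#' kinematic and EMG analyses per cycle, compares event timings between
#' behaviours with the circular decision tree, fits the mixed-effects
#' comparison tables, analyses a fluorescence table, and (optionally)
#' writes every output table plus a JSON run manifest with row counts and
#' file checksums. Deterministic given `config$seed`.
#'
#' @param config A [gait_sim_config()].
#' @param out_dir Output directory for CSV tables and the manifest;
#'   `NULL` (default) skips writing.
#' @param fluor_effect_d,fluor_slope Parameters of the simulated
#'   fluorescence experiment.
#' @param hr_reps,kuiper_reps Monte-Carlo sizes inside the circular tests.
#' @return List with `kinematics`, `emg`, `timings`, `circ_results`,
#'   `lme_tables`, `fluorescence`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         fluor_effect_d = 1, fluor_slope = 0.1,
                         hr_reps = 1000, kuiper_reps = 200) {
  stopifnot(inherits(config, "gait_sim_config"))
  warnings_log <- character(0)
  note <- function(...) warnings_log <<- c(warnings_log, sprintf(...))

  trials <- list()
  for (f in seq_len(config$n_fish))
    for (b in config$behaviours)
      trials[[paste(f, b, sep = "_")]] <-
        withCallingHandlers(
          simulate_trial(config, fish = f, behaviour = b),
          warning = function(w) {
            note("simulate %s/%s: %s", f, b, conditionMessage(w))
            invokeRestart("muffleWarning")
          })

  # ---- kinematics ------------------------------------------------------
  kin <- do.call(rbind, lapply(trials, function(tr) {
    cyc <- tr$cycles
    cyc$fish <- tr$fish
    k <- suppressWarnings(cycle_kinematics(tr$trajectories, cyc))
    k
  }))
  rownames(kin) <- NULL

  # ---- EMG: process channels, normalize per fish x muscle --------------
  processed <- lapply(trials, function(tr)
    lapply(tr$channels, process_channel))
  all_bursts <- list()
  for (key in names(processed))
    for (mus in names(processed[[key]])) {
      b <- processed[[key]][[mus]]$bursts
      if (nrow(b) > 0) {
        b$fish <- trials[[key]]$fish; b$muscle <- mus
        b$behaviour <- trials[[key]]$behaviour
        all_bursts[[paste(key, mus)]] <- b
      }
    }
  bursts <- do.call(rbind, all_bursts)
  rownames(bursts) <- NULL

  # first pass: unnormalized per-cycle summaries
  emg_rows <- list(); timing_rows <- list()
  for (key in names(processed)) {
    tr <- trials[[key]]
    for (mus in names(processed[[key]])) {
      cs <- emg_cycle_summary(processed[[key]][[mus]], tr$cycles)
      s <- cs$summary
      s$fish <- tr$fish; s$muscle <- mus
      emg_rows[[paste(key, mus)]] <- s
      ti <- cs$timings
      if (nrow(ti) > 0) {
        ti$fish <- tr$fish; ti$muscle <- mus
        timing_rows[[paste(key, mus)]] <- ti
      }
    }
  }
  emg <- do.call(rbind, emg_rows)
  timings <- do.call(rbind, timing_rows)
  rownames(emg) <- rownames(timings) <- NULL

  # second pass: normalize against the per-channel (fish x muscle) maximum
  # amplitude recorded across all trials and both behaviours
  emg <- do.call(rbind, lapply(split(emg, emg[, c("fish", "muscle")]),
                               function(ch) {
    nrm <- channel_normalization(ch$amp_raw)
    normalize_emg_summary(ch, nrm)
  }))
  rownames(emg) <- NULL

  # ---- circular timing comparisons ------------------------------------
  circ_results <- list()
  for (mus in unique(timings$muscle)) {
    for (ev in c("onset", "offset")) {
      a <- timings$deg[timings$muscle == mus & timings$event == ev &
                         timings$behaviour == "swimming"]
      b <- timings$deg[timings$muscle == mus & timings$event == ev &
                         timings$behaviour == "walking"]
      if (length(a) < 5 || length(b) < 5) next
      tree <- timing_decision_tree(a, b, kuiper_reps = kuiper_reps,
                                   hr_reps = hr_reps,
                                   seed = config$seed + length(circ_results))
      circ_results[[paste(mus, ev)]] <- data.frame(
        muscle = mus, event = ev,
        n_swim = length(a), n_walk = length(b),
        mean_swim = tree$sample_a$summary$mean_deg,
        mean_walk = tree$sample_b$summary$mean_deg,
        test = if (!is.null(tree$comparison)) tree$comparison$test else NA,
        statistic = if (!is.null(tree$comparison)) tree$comparison$statistic else NA,
        p = if (!is.null(tree$comparison)) tree$comparison$p else NA,
        trace = paste(tree$selection_trace, collapse = "; ")
      )
    }
  }
  circ <- do.call(rbind, circ_results)
  rownames(circ) <- NULL

  # ---- mixed-effects tables -------------------------------------------
  lme_tables <- list()
  kin_long <- kin[, c("fish", "behaviour", "pect_swing")]
  fitk <- fit_lme(kin_long, pect_swing ~ behaviour)
  lme_tables$kinematics <- list(
    anova = anova_table(fitk),
    emmeans = emmeans_table(fitk, ~ behaviour))
  emg_full <- emg[emg$scope == "full_cycle" & is.finite(emg$duty_factor_pct), ]
  fite <- fit_lme(emg_full, duty_factor_pct ~ behaviour * muscle)
  lme_tables$emg_duty <- list(
    anova = anova_table(fite),
    emmeans = emmeans_table(fite, ~ behaviour | muscle),
    pairwise = pairwise_bonferroni(fite, ~ behaviour | muscle))

  # ---- fluorescence ----------------------------------------------------
  fl <- generate_fluorescence(effect_d = fluor_effect_d,
                              gradient_slope = fluor_slope,
                              seed = config$seed + 77L)
  fluor <- evans_blue_analysis(fl$table)

  result <- list(kinematics = kin, emg = emg, timings = timings,
                 circ_results = circ, lme_tables = lme_tables,
                 fluorescence = fluor)

  manifest <- list(
    config = config[setdiff(names(config), c("burst_schedule"))],
    burst_schedule = config$burst_schedule,
    seed = config$seed,
    n_trials = length(trials),
    rows = list(kinematics = nrow(kin), emg = nrow(emg),
                timings = nrow(timings), circ_results = nrow(circ)),
    warnings = warnings_log
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(kinematics = "cycle_kinematics.csv",
               emg = "cycle_emg.csv",
               timings = "burst_timings.csv",
               circ_results = "circular_tests.csv")
    for (nm in names(files))
      write.csv(result[[nm]], file.path(out_dir, files[[nm]]),
                row.names = FALSE)
    write.csv(lme_tables$kinematics$anova,
              file.path(out_dir, "lme_kinematics_anova.csv"), row.names = FALSE)
    write.csv(lme_tables$emg_duty$anova,
              file.path(out_dir, "lme_emg_anova.csv"), row.names = FALSE)
    write.csv(fluor$effect_sizes,
              file.path(out_dir, "fluorescence_effects.csv"), row.names = FALSE)
    manifest$checksums <- as.list(tools::md5sum(
      list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)))
    names(manifest$checksums) <- basename(names(manifest$checksums))
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  result$manifest <- manifest
  result
}

# ---- table I/O with schema validation ---------------------------------

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0)
    stop(what, ": missing column(s) ", paste(missing, collapse = ", "))
  df
}

#' Read / write the pipeline's tabular formats
#'
#' CSV readers with schema validation (column presence, angle ranges, time
#' ordering); violations are reported with the offending column and row.
#' Writers are plain CSV (`row.names = FALSE`), so write-then-read is the
#' identity on all typed fields.
#'
#' @param path File path.
#' @return The validated data frame.
#' @export
read_trajectories <- function(path) {
  df <- read.csv(path)
  check_columns(df, c("time_s", "landmark", "x", "y", "z"), "trajectory table")
  df
}

#' @rdname read_trajectories
#' @export
read_cycles <- function(path) {
  df <- read.csv(path)
  check_columns(df, c("behaviour", "t_start", "t_mid", "t_end"), "cycle table")
  bad <- which(!(df$t_start < df$t_mid & df$t_mid < df$t_end))
  if (length(bad) > 0)
    stop("cycle table: t_start < t_mid < t_end violated at row ", bad[1])
  df
}

#' @rdname read_trajectories
#' @export
read_angles <- function(path) {
  df <- read.csv(path)
  check_columns(df, c("deg"), "angle table")
  bad <- which(!is.finite(df$deg) | df$deg < 0 | df$deg >= 360)
  if (length(bad) > 0)
    stop("angle table: column 'deg' outside [0, 360) at row ", bad[1])
  df
}

#' @rdname read_trajectories
#' @param df Data frame to write.
#' @export
write_table <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
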
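#' Generate a nested observation table with known fixed effects
#'
#' Produces a tidy per-cycle table for one response variable under the
#' study design: `value = grand_mean + behaviour_effect (walking) +
#' muscle_effect + interaction (walking only) + fish intercept + residual`,
#' with the fish intercepts drawn Normal(0, `random_fish_sd`) and iid
#' Normal residuals. The generating effects are returned as ground truth so
#' mixed-model recovery can be checked.
#'
#' @param config A [gait_sim_config()]; uses `n_fish`, `cycles_per_fish`,
#'   `behaviours`, `random_fish_sd` and `study_effects`.
#' @param variable Name recorded in the `variable` column.
#' @param muscles Muscle labels crossed with the design; set to `NULL` for
#'   a kinematic-style table without a muscle factor.
#' @param seed Integer seed (default `config$seed`).
#' @return List with `table` (data frame: fish, behaviour, muscle, cycle,
#'   variable, value) and `truth` (the effect values and the drawn fish
#'   intercepts).
#' @export
generate_study <- function(config, variable = "response",
                           muscles = FIN_MUSCLES, seed = config$seed) {
  stopifnot(inherits(config, "gait_sim_config"))
  eff <- config$study_effects
  set.seed(seed)
  intercepts <- rnorm(config$n_fish, 0, config$random_fish_sd)
  mus <- if (is.null(muscles)) NA_character_ else muscles
  grid <- expand.grid(
    cycle = seq_len(config$cycles_per_fish),
    muscle = mus,
    behaviour = config$behaviours,
    fish = seq_len(config$n_fish),
    stringsAsFactors = FALSE
  )
  walk <- as.numeric(grid$behaviour == "walking")
  mus_eff <- if (is.null(muscles)) 0 else unname(eff$muscle_effects[grid$muscle])
  int_eff <- if (is.null(muscles)) 0 else unname(eff$interaction[grid$muscle]) * walk
  mu <- eff$grand_mean + eff$behaviour_effect * walk + mus_eff + int_eff +
    intercepts[grid$fish]
  grid$variable <- variable
  grid$value <- mu + rnorm(nrow(grid), 0, eff$residual_sd)
  grid <- grid[, c("fish", "behaviour", "muscle", "cycle", "variable", "value")]
  list(table = grid,
       truth = list(grand_mean = eff$grand_mean,
                    behaviour_effect = eff$behaviour_effect,
                    muscle_effects = eff$muscle_effects,
                    interaction = eff$interaction,
                    residual_sd = eff$residual_sd,
                    fish_intercepts = intercepts))
}

#' Generate an Evans Blue fluorescence cell table
#'
#' Cell-level integrated fluorescence densities with a treatment shift of
#' `effect_d` pooled standard deviations (Cohen's d), a linear
#' proximo-distal gradient along the fin, and a per-section constant
#' background that the analysis must subtract.
#'
#' @param effect_d True standardized treatment effect (walked - control).
#' @param gradient_slope Intensity change per percent fin length.
#' @param n_cells Cells per fish x muscle section (>= 2).
#' @param seed Integer seed.
#' @param n_fish Fish per treatment group.
#' @param size_class Size-class label stamped on the table.
#' @param muscles Muscle labels.
#' @param baseline Mean background-free intensity of control cells at 0%
#'   fin length.
#' @param cell_sd Cell-to-cell intensity standard deviation (the scale unit
#'   of `effect_d`).
#' @return List with `table` (fish, size_class, treatment, muscle,
#'   pct_fin_length, cell_intensity, background) and `truth`.
#' @export
generate_fluorescence <- function(effect_d, gradient_slope = 0, n_cells = 50,
                                  seed = 1L, n_fish = 4,
                                  size_class = "small",
                                  muscles = FIN_MUSCLES,
                                  baseline = 100, cell_sd = 20) {
  stopifnot(n_cells >= 2, n_fish >= 1)
  set.seed(seed)
  rows <- list()
  fish_id <- 0L
  for (treatment in c("control", "walked")) {
    for (f in seq_len(n_fish)) {
      fish_id <- fish_id + 1L
      for (mus in muscles) {
        background <- runif(1, 20, 40)   # constant within a section
        pct <- runif(n_cells, 0, 100)
        signal <- baseline + effect_d * cell_sd * (treatment == "walked") +
          gradient_slope * pct + rnorm(n_cells, 0, cell_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          fish = fish_id, size_class = size_class, treatment = treatment,
          muscle = mus, pct_fin_length = pct,
          cell_intensity = background + signal, background = background
        )
      }
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab,
       truth = list(effect_d = effect_d, gradient_slope = gradient_slope,
                    baseline = baseline, cell_sd = cell_sd))
}
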
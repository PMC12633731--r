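test_that("zero-variance data recover fixed effects exactly", {
  cfg <- tiny_config(random_fish_sd = 0)
  cfg$study_effects$residual_sd <- 1e-8
  st <- generate_study(cfg, muscles = NULL)
  fit <- fit_lme(st$table, value ~ behaviour)
  em <- emmeans_table(fit, ~ behaviour)
  expect_equal(em$emmean[em$behaviour == "walking"] -
                 em$emmean[em$behaviour == "swimming"],
               st$truth$behaviour_effect, tolerance = 1e-4)
})

test_that("balanced-design emmeans equal arithmetic group means", {
  cfg <- gait_sim_config(n_fish = 4, cycles_per_fish = 6, seed = 31)
  st <- generate_study(cfg)
  fit <- fit_lme(st$table, value ~ behaviour * muscle)
  em <- emmeans_table(fit, ~ behaviour)
  means <- tapply(st$table$value, st$table$behaviour, mean)
  for (b in names(means))
    expect_equal(em$emmean[em$behaviour == b], unname(means[b]),
                 tolerance = 1e-10)
  em2 <- emmeans_table(fit, ~ muscle)
  means2 <- tapply(st$table$value, st$table$muscle, mean)
  for (m in names(means2))
    expect_equal(em2$emmean[em2$muscle == m], unname(means2[m]),
                 tolerance = 1e-10)
})

test_that("unbalanced emmeans match a prediction-grid oracle", {
  cfg <- gait_sim_config(n_fish = 4, cycles_per_fish = 6, seed = 32)
  st <- generate_study(cfg)
  tab <- st$table
  # drop 30% of walking rows to unbalance the design
  set.seed(32)
  drop <- which(tab$behaviour == "walking")
  tab <- tab[-sample(drop, round(0.3 * length(drop))), ]
  fit <- fit_lme(tab, value ~ behaviour * muscle)
  em <- emmeans_table(fit, ~ behaviour)
  # oracle: average the fixed-effect predictions over a balanced grid
  beta <- nlme::fixef(fit$model)
  grid <- expand.grid(behaviour = c("swimming", "walking"),
                      muscle = FIN_MUSCLES, stringsAsFactors = FALSE)
  X <- stats::model.matrix(~ behaviour * muscle, grid)
  pred <- as.numeric(X %*% beta)
  for (b in c("swimming", "walking"))
    expect_equal(em$emmean[em$behaviour == b],
                 mean(pred[grid$behaviour == b]), tolerance = 1e-8)
})

test_that("recovery study: estimates unbiased within Monte-Carlo error", {
  cfg <- gait_sim_config()
  ests <- vapply(1:60, function(r) {
    st <- generate_study(cfg, muscles = NULL, seed = 5000 + r)
    fit <- fit_lme(st$table, value ~ behaviour)
    unname(nlme::fixef(fit$model)["behaviourwalking"])
  }, numeric(1))
  mc_se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - cfg$study_effects$behaviour_effect), 3 * mc_se)
})

test_that("anova table equals the classical ANOVA oracle without random effects", {
  cfg <- gait_sim_config(n_fish = 4, cycles_per_fish = 5, random_fish_sd = 0,
                         seed = 33)
  st <- generate_study(cfg, muscles = NULL)
  fit <- fit_lme(st$table, value ~ behaviour, random = NULL)
  a <- anova_table(fit)
  oracle <- summary(stats::aov(value ~ behaviour, data = st$table))[[1]]
  expect_equal(a$F[a$term == "behaviour"], oracle$`F value`[1],
               tolerance = 1e-10)
  expect_equal(a$p[a$term == "behaviour"], oracle$`Pr(>F)`[1],
               tolerance = 1e-10)
  expect_equal(a$df_den, oracle$Df[2])
})

test_that("mixed-model anova reports containment df and R2m <= R2c", {
  cfg <- gait_sim_config(seed = 34)
  st <- generate_study(cfg)
  fit <- fit_lme(st$table, value ~ behaviour * muscle)
  a <- anova_table(fit)
  expect_setequal(a$term, c("behaviour", "muscle", "behaviour:muscle"))
  expect_true(all(a$F >= 0))
  expect_true(all(a$p >= 0 & a$p <= 1))
  expect_true(all(a$R2m <= a$R2c + 1e-12))
  # containment df: within-fish terms are tested against observation-level
  # slots, not the handful of fish
  expect_true(all(a$df_den > cfg$n_fish & a$df_den < nrow(st$table)))
})

test_that("anova type-I error is controlled under the null", {
  cfg <- gait_sim_config(n_fish = 4, cycles_per_fish = 8)
  cfg$study_effects$behaviour_effect <- 0
  rej <- vapply(1:200, function(r) {
    st <- generate_study(cfg, muscles = NULL, seed = 40000 + r)
    fit <- fit_lme(st$table, value ~ behaviour)
    anova_table(fit)$p[1] < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("Bonferroni correction caps and scales raw p-values", {
  cfg <- gait_sim_config(seed = 35)
  st <- generate_study(cfg)
  fit <- fit_lme(st$table, value ~ behaviour * muscle)
  pw <- pairwise_bonferroni(fit, ~ muscle | behaviour)
  expect_equal(nrow(pw), 12)   # 6 muscle pairs x 2 behaviours
  expect_equal(pw$p_bonf, pmin(1, pw$p * 12), tolerance = 1e-12)
  expect_true(all(pw$p_bonf >= pw$p))
  pw1 <- pairwise_bonferroni(fit, ~ muscle | behaviour, m = 1)
  expect_equal(pw1$p_bonf, pmin(1, pw1$p), tolerance = 1e-12)
})

test_that("Cohen's d matches the pooled-sd formula", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  x <- c(0, 2); y <- c(-2, 0)   # means differ by exactly one pooled sd
  expect_equal(cohens_d(x, y), sqrt(2))
  set.seed(36)
  a <- rnorm(30, 1, 2); b <- rnorm(40, 0, 2)
  sp <- sqrt(((29) * var(a) + 39 * var(b)) / 68)
  expect_equal(cohens_d(a, b), (mean(a) - mean(b)) / sp, tolerance = 1e-12)
  expect_error(cohens_d(c(1, 1), c(1, 1)), "pooled")
})

test_that("singular mixed fits fall back to a blocked fixed-effects model", {
  # a single observation per fish x behaviour with no replication makes the
  # mixed fit fragile; the wrapper must still return a usable fit
  d <- data.frame(fish = rep(1:2, each = 2),
                  behaviour = rep(c("swimming", "walking"), 2),
                  value = c(1, 2, 1.1, 2.1))
  fit <- suppressWarnings(fit_lme(d, value ~ behaviour))
  expect_s3_class(fit, "fin_lme")
  expect_true(fit$converged || fit$fallback)
})

test_that("Evans Blue analysis subtracts background and respects contracts", {
  fl <- generate_fluorescence(effect_d = 0, gradient_slope = 0,
                              n_cells = 80, seed = 37)
  an <- evans_blue_analysis(fl$table)
  tr_row <- an$models[an$models$term == "treatmentwalked", ]
  expect_lt(abs(tr_row$estimate), 3 * tr_row$se)
  expect_lt(max(abs(an$effect_sizes$cohens_d)), 0.4)
  # negative background-subtracted intensities are kept (no clipping)
  tab <- fl$table
  set.seed(38)
  tab$cell_intensity <- tab$background - 5 + rnorm(nrow(tab), 0, 0.5)
  an2 <- evans_blue_analysis(tab)
  expect_true(all(an2$muscle_means$intensity < 0))
  # a single-treatment size class is skipped with a warning
  solo <- fl$table[fl$table$treatment == "walked", ]
  expect_warning(an3 <- evans_blue_analysis(solo), "single treatment")
  expect_null(an3$models)
  # interaction model exposes the distance x treatment term
  an4 <- evans_blue_analysis(fl$table, interaction = TRUE)
  expect_true("pct_fin_length:treatmentwalked" %in% an4$models$term)
})
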
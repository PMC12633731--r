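#!/usr/bin/env Rscript
# Mixed-effects comparison tables: behaviour effects on kinematics (random
# fish intercept) and behaviour x muscle effects on EMG duty factor, with
# estimated marginal means and Bonferroni pairwise contrasts.

library(finmotor)

kin <- read.csv("results/cycle_kinematics.csv")
emg <- read.csv("results/cycle_emg.csv")

dir.create("results", showWarnings = FALSE)

for (v in c("pect_swing", "add_range", "add_vel_max")) {
  fit <- fit_lme(kin, as.formula(paste(v, "~ behaviour")))
  a <- anova_table(fit)
  a$variable <- v
  em <- emmeans_table(fit, ~ behaviour)
  cat(sprintf("%-12s F = %7.2f (df %d,%d)  p = %.3g  R2m = %.2f  R2c = %.2f\n",
              v, a$F[1], a$df_num[1], a$df_den[1], a$p[1], a$R2m[1], a$R2c[1]))
  cat(sprintf("   emmean swimming %.3f +/- %.3f | walking %.3f +/- %.3f\n",
              em$emmean[em$behaviour == "swimming"], em$sem[em$behaviour == "swimming"],
              em$emmean[em$behaviour == "walking"], em$sem[em$behaviour == "walking"]))
  write_table(a, paste0("results/lme_kin_", v, "_anova.csv"))
  write_table(em, paste0("results/lme_kin_", v, "_emmeans.csv"))
}

full <- emg[emg$scope == "full_cycle" & is.finite(emg$duty_factor_pct), ]
fit <- fit_lme(full, duty_factor_pct ~ behaviour * muscle)
a <- anova_table(fit)
write_table(a, "results/lme_emg_duty_anova.csv")
em <- emmeans_table(fit, ~ behaviour | muscle)
write_table(em, "results/lme_emg_duty_emmeans.csv")
pw <- pairwise_bonferroni(fit, ~ muscle | behaviour)
write_table(pw, "results/lme_emg_duty_pairwise.csv")
cat("\nEMG duty factor (% full cycle):\n")
print(a, digits = 3)
print(em)
cat("Pairwise muscle contrasts (Bonferroni family of", nrow(pw), "):\n")
print(head(pw[order(pw$p_bonf), ], 6), digits = 3)
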
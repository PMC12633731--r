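#!/usr/bin/env Rscript
# Evans Blue fluorescence analysis on a simulated cell-intensity table:
# background subtraction, per-size-class linear models with distance along
# the fin and treatment as predictors, and Cohen's d per muscle.

library(finmotor)

dir.create("results", showWarnings = FALSE)

fl_small <- generate_fluorescence(effect_d = 1.0, gradient_slope = 0.15,
                                  n_cells = 60, seed = 101,
                                  size_class = "small")
fl_large <- generate_fluorescence(effect_d = 0.1, gradient_slope = 0.05,
                                  n_cells = 40, seed = 102, n_fish = 3,
                                  size_class = "large")
tab <- rbind(fl_small$table, fl_large$table)
an <- evans_blue_analysis(tab)

write_table(an$models, "results/evans_blue_models.csv")
write_table(an$effect_sizes, "results/evans_blue_effects.csv")

cat("Treatment (walked vs control) coefficients per size class:\n")
print(an$models[an$models$term == "treatmentwalked", ], digits = 3)
cat("\nCohen's d per muscle:\n")
print(an$effect_sizes, digits = 2)
cat("\nSmall fish show a clear treatment effect (d near the simulated 1.0);",
    "large fish, simulated with a weak effect, do not separate reliably —",
    "the same qualitative size pattern the damage assay is sensitive to.\n")
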
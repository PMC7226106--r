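#!/usr/bin/env Rscript
# Step 2 — clinical relevance of the age and sex covariates.
#
# Simulates 1000 virtual patients per group (men/women aged 20/90) on
# dabrafenib 150 mg twice daily and summarizes the composite steady-state
# exposure AUC_DAB + AUC_OHD computed by the classic dose/clearance
# equations.  The typical (closed-form) values are reported next to the
# simulated medians: the contrast shows the dominant age effect (roughly a
# doubling of composite exposure from age 20 to age 90) and the smaller
# sex effect (women about 11% higher than men).
suppressPackageStartupMessages(library(dabtrapk))

dir.create("results", showWarnings = FALSE)
pop <- pop_dabohd()

f3 <- simulate_covariate_impact(pop, n = 1000, seed = 202)
f0 <- simulate_covariate_impact(pop, n = 1, seed = 1, iiv = FALSE)
f3$typical <- f0$median[match(f3$label, f0$label)]
write.csv(f3, "results/composite_auc_by_covariates.csv", row.names = FALSE)

message("composite steady-state AUC (ng*h/mL), 150 mg BID:")
for (g in seq_len(nrow(f3)))
  message(sprintf("  %-9s median %7.0f (95%% interval %7.0f-%7.0f), typical %7.0f",
                  f3$label[g], f3$median[g], f3$lower[g], f3$upper[g],
                  f3$typical[g]))
message(sprintf("age effect (men): %0.0f%% higher at 90 vs 20; sex effect: %0.0f%% reduction in CL/F for women",
                100 * (f3$median[f3$label == "man 90"] /
                         f3$median[f3$label == "man 20"] - 1),
                100 * (1 - pop$theta_sex_cl)))
message("wrote results/composite_auc_by_covariates.csv")
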
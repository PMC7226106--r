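#!/usr/bin/env Rscript
# Step 5 — exposure-toxicity and exposure-survival analysis.
#
# Synthetic outcomes are generated from the cohort's true exposures (the
# DLT probability rises with AUC_DAB; overall survival worsens with ECOG
# PS >= 2 and a metabolic ratio >= 1; progression-free survival with >= 3
# metastatic sites and cerebral metastases).  The statistical stage then
# analyses the MAP-estimated exposures exactly as the study design
# prescribes: rank-sum/Fisher contrasts of DLT vs non-DLT patients (last
# pre-DLT AUC vs treatment-course average), and univariate plus stepwise
# multivariate Cox models with the documented variable codings.
suppressPackageStartupMessages(library(dabtrapk))

spec <- cohort_spec(n = 52, seed = 101)
covs <- read.csv("results/cohort_covariates.csv")
truth <- read.csv("results/cohort_truth.csv")
expo_map <- read.csv("results/exposures_map.csv")
m3 <- read.csv("results/exposures_auc_m3.csv")

cohort <- list(spec = spec, covariates = covs)
truth_expo <- exposure_summary(truth)
outcomes <- generate_outcomes(cohort, truth_expo, spec)
write.csv(outcomes, "results/outcomes.csv", row.names = FALSE)

## exposure-toxicity: DLT vs non-DLT contrast on MAP-estimated exposures
for (v in c("auc_dab", "auc_ohd", "auc_composite")) {
  r <- dlt_exposure_contrast(expo_map, outcomes, "DAB", v)
  message(sprintf("DLT contrast %-13s: DLT median %8.0f vs %8.0f (p = %.4f, %s)",
                  v, r$summary$median[1], r$summary$median[2], r$p, r$test))
}
r_tra <- dlt_exposure_contrast(expo_map, outcomes, "TRA", "auc_tra")
message(sprintf("DLT contrast %-13s: DLT median %8.0f vs %8.0f (p = %.4f)",
                "auc_tra (TRA)", r_tra$summary$median[1],
                r_tra$summary$median[2], r_tra$p))

## exposure-survival: Cox models on AUC_M3 aggregates
surv <- merge(outcomes, m3, by = "id")
surv$ratio_ge_1 <- surv$ratio_ge_1.y   # exposure-derived coding
for (ep in c("os", "pfs")) {
  a <- survival_analysis(surv, ep)
  tab <- a$univariate
  write.csv(tab, sprintf("results/cox_%s_univariate.csv", ep),
            row.names = FALSE)
  message(sprintf("%s: %d events / %d patients; univariate p < 0.05: %s",
                  toupper(ep), a$n_events, a$n,
                  paste(tab$variable[!is.na(tab$p) & tab$p < 0.05],
                        collapse = ", ")))
  if (!is.null(a$multivariate)) {
    write.csv(a$multivariate, sprintf("results/cox_%s_multivariate.csv", ep),
              row.names = FALSE)
    for (k in seq_len(nrow(a$multivariate)))
      message(sprintf("  multivariate %-14s HR %.2f (%.2f-%.2f), p = %.4f",
                      a$multivariate$variable[k], a$multivariate$hr[k],
                      a$multivariate$lo[k], a$multivariate$hi[k],
                      a$multivariate$p[k]))
  }
}
message("wrote results/outcomes.csv and the cox_* tables")
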
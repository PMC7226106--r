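#!/usr/bin/env Rscript
# Step 1 — build the virtual study cohort.
#
# The real cohort (73 patients for model building, 52 for the PK/PD stage)
# is not public, so the whole analysis runs on a synthetic cohort with the
# same covariate marginals, regimens (dabrafenib 150 mg BID + trametinib
# 2 mg QD), and sparse therapeutic-drug-monitoring design (median 2 samples
# in the first three months).  Concentrations are simulated from the final
# population models with full interindividual, interoccasion and residual
# variability; the generating truth (individual clearances and AUCs) is
# kept alongside so later steps can report recovery error.
suppressPackageStartupMessages(library(dabtrapk))

dir.create("results", showWarnings = FALSE)
seed <- 101
n <- 52

spec <- cohort_spec(n = n, seed = seed)
coh <- generate_cohort(spec)
sim <- simulate_cohort(simulation_spec(coh$covariates, coh$occasions,
                                       seed = seed + 1L),
                       pop_dabohd(), pop_tra())

write_event_table(sim$events, "results/cohort_events.csv")
write.csv(sim$truth, "results/cohort_truth.csv", row.names = FALSE)
write.csv(coh$covariates, "results/cohort_covariates.csv", row.names = FALSE)

obs <- sim$events[sim$events$EVID == 0L, ]
message(sprintf("simulated %d patients, %d concentration records (%d DAB, %d OHD, %d TRA)",
                n, nrow(obs), sum(obs$ANALYTE == "DAB"),
                sum(obs$ANALYTE == "OHD"), sum(obs$ANALYTE == "TRA")))
message(sprintf("median sampling occasions per patient: %d",
                median(table(coh$occasions$id))))
message("wrote results/cohort_events.csv, cohort_truth.csv, cohort_covariates.csv")
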
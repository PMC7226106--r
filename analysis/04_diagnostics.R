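#!/usr/bin/env Rscript
# Step 4 — model qualification on the simulated cohort.
#
# A prediction-corrected visual predictive check compares the observed
# percentiles with bands from 500 model simulations under the cohort's own
# designs (data simulated from the model should sit inside the bands), and
# a subject-resampling bootstrap of the naive-pooled trametinib fit gives
# percentile intervals for the fixed effects (200 replicates; the full
# analysis used 500).
suppressPackageStartupMessages(library(dabtrapk))

events <- blq_filter(read_event_table("results/cohort_events.csv"))

v <- pcvpc(events, pop_dabohd(), n_sim = 500, bins = 6, seed = 401)
write.csv(as.data.frame(v), "results/pcvpc_dabohd.csv", row.names = FALSE)
inside <- v$obs_p50 >= v$sim_p50_lo & v$obs_p50 <= v$sim_p50_hi
message(sprintf("pcVPC (DAB/OHD): observed median inside the simulated 90%% band in %d/%d bins; %d observation(s) excluded",
                sum(inside), length(inside), attr(v, "n_excluded")))

fitter <- function(ev) fit_naive_pooled(ev, "tra", jitter = 0.05, seed = 7,
                                        steady_state = TRUE)$estimates
b <- bootstrap_fit(events, n_rep = 200, fitter = fitter, seed = 402)
boot <- data.frame(parameter = names(b$median), median = b$median,
                   lo2.5 = b$ci[1, ], hi97.5 = b$ci[2, ])
write.csv(boot, "results/bootstrap_tra.csv", row.names = FALSE)
message(sprintf("bootstrap (TRA, %d replicates, %d failed): CL/F median %.2f L/h (95%% PI %.2f-%.2f)",
                nrow(b$estimates), b$n_failed, b$median["cl"],
                b$ci[1, "cl"], b$ci[2, "cl"]))
message("wrote results/pcvpc_dabohd.csv, bootstrap_tra.csv")
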
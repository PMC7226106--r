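# Exposure-toxicity contrasts and Cox survival analysis with the study's
# variable codings.

# A ready-made synthetic analysis set: cohort, truth exposures and outcomes
# (generator defaults unless overridden).
pkpd_dataset <- function(n, seed, ...) {
  spec <- cohort_spec(n = n, seed = seed, ...)
  coh <- generate_cohort(spec)
  dr <- draw_random_effects(pop_dabohd(), n, seed = seed + 1000L)
  expo <- do.call(rbind, lapply(seq_len(n), function(i) {
    ind <- apply_covariates(pop_dabohd(),
                            covariates(coh$covariates$age[i],
                                       coh$covariates$sex[i]),
                            re_for_subject(dr, i))
    o <- coh$occasions[coh$occasions$id == coh$covariates$id[i], ]
    data.frame(id = o$id, occ = o$occ, day = o$day,
               dose_dab = o$dose_dab, cl_dab = ind$cl, cl_ohd = ind$clm)
  }))
  expo <- exposure_summary(expo)
  out <- generate_outcomes(coh, expo, spec)
  list(spec = spec, cohort = coh, exposures = expo, outcomes = out)
}

surv_data <- function(ds) {
  m3 <- auc_m3_cohort(ds$exposures)
  out <- ds$outcomes
  out$ratio_ge_1 <- NULL   # keep the exposure-derived coding from AUC_M3
  merge(out, m3, by = "id")
}

test_that("dichotomizations include their boundaries", {
  d <- code_covariates(data.frame(ecog_ps = c(1, 2, 3),
                                  n_met_sites = c(2, 3, 5),
                                  ldh_ratio = c(1.49, 1.5, 2),
                                  auc_m3_ratio = c(0.99, 1, 1.2)))
  expect_equal(d$ecog_ge2, c(0L, 1L, 1L))
  expect_equal(d$sites_ge3, c(0L, 1L, 1L))
  expect_equal(d$ldh_ge15, c(0L, 1L, 1L))
  expect_equal(d$ratio_ge_1, c(0L, 1L, 1L))
})

test_that("identical exposure distributions give p = 1 and empty groups error", {
  expo <- data.frame(id = sprintf("P%d", 1:6), occ = 1, day = 30,
                     auc_dab = rep(c(5000, 7000, 9000), 2))
  out <- data.frame(id = sprintf("P%d", 1:6), dlt_dab = rep(c(1, 0), each = 3),
                    dlt_dab_day = c(60, 60, 60, NA, NA, NA))
  r <- dlt_exposure_contrast(expo, out, "DAB", "auc_dab")
  expect_equal(r$p, 1)
  expect_equal(r$summary$median, c(7000, 7000))
  out0 <- out; out0$dlt_dab <- 0
  expect_error(dlt_exposure_contrast(expo, out0, "DAB"), "DLT group")
  out1 <- out; out1$dlt_dab <- 1; out1$dlt_dab_day <- 60
  expect_error(dlt_exposure_contrast(expo, out1, "DAB"), "non-DLT group")
})

test_that("DLT patients contribute the last pre-onset exposure, others their mean", {
  expo <- data.frame(id = rep(c("A", "B"), each = 3), occ = rep(1:3, 2),
                     day = rep(c(20, 50, 80), 2),
                     auc_dab = c(8000, 9000, 2000, 6000, 7000, 8000))
  out <- data.frame(id = c("A", "B"), dlt_dab = c(1, 0),
                    dlt_dab_day = c(55, NA))
  v <- dabtrapk:::dlt_exposure_values(expo, out, "dlt_dab", "dlt_dab_day",
                                      "auc_dab")
  expect_equal(v$value[v$id == "A"], 9000)   # last occasion before day 55
  expect_equal(v$value[v$id == "B"], 7000)   # mean over the course
})

test_that("a planted exposure-toxicity link is detected in a study-sized cohort", {
  # DLT probability rises with AUC_DAB (logistic link, default slope);
  # the rank-sum contrast should find the DLT group overexposed in most
  # replications at n = 52
  hits <- 0; n_seeds <- 50
  for (s in seq_len(n_seeds)) {
    ds <- pkpd_dataset(52, seed = 5000 + s)
    r <- tryCatch(dlt_exposure_contrast(ds$exposures, ds$outcomes, "DAB",
                                        "auc_dab"),
                  error = function(e) NULL)
    if (is.null(r)) next
    if (r$summary$median[1] > r$summary$median[2] && r$p < 0.05)
      hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.8)
})

test_that("binary baseline factors use the exact contingency test", {
  expo <- data.frame(id = sprintf("P%d", 1:8), occ = 1, day = 30,
                     auc_dab = 7000)
  out <- data.frame(id = sprintf("P%d", 1:8), dlt_dab = rep(c(1, 0), 4),
                    dlt_dab_day = rep(c(60, NA), 4), ppi = c(1, 1, 0, 0, 1, 0, 1, 0))
  r <- dlt_exposure_contrast(expo, out, "DAB", "ppi")
  expect_equal(r$test, "Fisher exact")
  expect_true(r$p > 0.05)
})

test_that("univariate Cox results are invariant to subject ordering", {
  ds <- pkpd_dataset(80, seed = 101)
  sd1 <- surv_data(ds)
  sd2 <- sd1[rev(seq_len(nrow(sd1))), ]
  a1 <- survival_analysis(sd1, "os")
  a2 <- survival_analysis(sd2, "os")
  expect_equal(a1$univariate$p, a2$univariate$p, tolerance = 1e-10)
  expect_equal(a1$univariate$hr, a2$univariate$hr, tolerance = 1e-10)
})

test_that("exposure hazard ratios are reported on the documented scale", {
  ds <- pkpd_dataset(120, seed = 102)
  sd1 <- surv_data(ds)
  a <- survival_analysis(sd1, "os")
  row <- a$univariate[a$univariate$variable == "auc_m3_ohd", ]
  expect_equal(row$scale, 1000)
  # refitting with pre-scaled exposure reproduces the HR
  sd3 <- sd1; sd3$auc_m3_ohd <- sd3$auc_m3_ohd / 1000
  fit <- survival::coxph(survival::Surv(os_months, os_event) ~ auc_m3_ohd,
                         data = sd3)
  expect_equal(unname(row$hr), unname(exp(coef(fit))), tolerance = 1e-8)
})

test_that("zero-event and degenerate datasets are guarded", {
  ds <- pkpd_dataset(30, seed = 103)
  sd1 <- surv_data(ds)
  sd1$os_event <- 0
  expect_error(survival_analysis(sd1, "os"), "no events")
  sd2 <- surv_data(ds); sd2$os_months[1] <- -1
  expect_error(survival_analysis(sd2, "os"), "negative")
})

test_that("the multivariate step keeps only variables below the threshold", {
  ds <- pkpd_dataset(250, seed = 104)
  sd1 <- surv_data(ds)
  a <- survival_analysis(sd1, "os")
  if (!is.null(a$multivariate)) {
    expect_true(all(a$multivariate$p < 0.05 | nrow(a$multivariate) == 1))
    expect_true(all(a$multivariate$variable %in%
                      a$univariate$variable[a$univariate$p < 0.05]))
  }
  # guard: too few events blocks the multivariate step
  few <- sd1[1:12, ]
  few$os_event[seq_len(nrow(few))] <- c(rep(1, 5), rep(0, 7))
  a2 <- survival_analysis(few, "os", min_events = 10)
  expect_null(a2$multivariate)
})
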
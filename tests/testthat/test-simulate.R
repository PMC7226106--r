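# Random-effect and residual-error generation, the covariate-impact
# simulation, and virtual-cohort datasets.

test_that("random-effect draws honour the lognormal CV mapping and the switches", {
  pop <- pop_dabohd()
  # CV = 0 (switch off) gives exactly zero deviates
  z <- draw_random_effects(pop, 50, seed = 1, n_occ = 2, iiv = FALSE,
                           iov = FALSE)
  expect_true(all(z$eta == 0))
  expect_true(all(z$kappa == 0))
  # Monte-Carlo check of the CV <-> omega mapping on the CV^2 scale
  d <- draw_random_effects(pop, 1e5, seed = 2)
  cv2 <- stats::var(exp(d$eta[, "clm"])) / mean(exp(d$eta[, "clm"]))^2
  expect_equal(cv2, 0.24^2, tolerance = 0.05)
  # identical seeds give bitwise-identical draws
  a <- draw_random_effects(pop, 100, seed = 33, n_occ = 3)
  b <- draw_random_effects(pop, 100, seed = 33, n_occ = 3)
  expect_identical(a, b)
})

test_that("residual errors reproduce the correlated proportional model", {
  pop <- pop_dabohd()
  # zero RUV: observed equals predicted
  p0 <- pop_dabohd(ruv_dab = 0, ruv_ohd = 0)
  o <- apply_residual_error(rep(100, 10), rep(80, 10), p0, seed = 1)
  expect_equal(o$dab, rep(100, 10))
  expect_equal(o$ohd, rep(80, 10))
  # empirical SDs and correlation of the error pairs at n = 1e5
  n <- 1e5
  o <- apply_residual_error(rep(1, n), rep(1, n), pop, seed = 4)
  e_dab <- o$dab - 1; e_ohd <- o$ohd - 1
  expect_equal(stats::cor(e_dab, e_ohd), 0.870, tolerance = 0.01)
  # multiplicative errors truncate at zero concentration (eps censored at -1)
  expect_true(all(o$dab >= 0) && all(o$ohd >= 0))
  expect_gte(min(e_dab), -1)
  # additive trametinib error SD
  t <- apply_residual_error_tra(rep(100, n), pop_tra(), seed = 5)
  expect_equal(stats::sd(t - 100), 4.14, tolerance = 0.02 * 4.14)
  # truncation at zero
  tt <- apply_residual_error_tra(rep(0.1, 1000), pop_tra(), seed = 6)
  expect_true(all(tt >= 0))
})

test_that("covariate-impact simulation matches closed-form typical exposures", {
  pop <- pop_dabohd()
  f0 <- simulate_covariate_impact(pop, n = 1, seed = 1, iiv = FALSE)
  # closed-form composite AUC for each group, from the covariate equations
  closed <- vapply(seq_len(nrow(f0)), function(g) {
    ind <- apply_covariates(pop, covariates(f0$age[g], f0$sex[g]))
    auc_interval(150, ind$cl, "DAB") + auc_interval(150, ind$clm, "OHD")
  }, numeric(1))
  expect_equal(f0$median, closed, tolerance = 1e-10)
  expect_equal(f0$median[f0$sex == 0 & f0$age == 20], 10483.5,
               tolerance = 1e-4)
})

test_that("simulated group medians converge to the typical values and order correctly", {
  pop <- pop_dabohd()
  f <- simulate_covariate_impact(pop, n = 1e5, seed = 7)
  f0 <- simulate_covariate_impact(pop, n = 1, seed = 1, iiv = FALSE)
  expect_equal(f$median, f0$median, tolerance = 0.01)
  # age 90 above age 20 within sex; women above men within age
  m <- function(s, a) f$median[f$sex == s & f$age == a]
  expect_gt(m(0, 90), m(0, 20))
  expect_gt(m(1, 90), m(1, 20))
  expect_gt(m(1, 20), m(0, 20))
  expect_gt(m(1, 90), m(0, 90))
})

test_that("cohort simulation without variability reproduces the typical profile", {
  des <- fixed_design(4, n_occ = 2)
  spec <- simulation_spec(des$covariates, des$occasions, seed = 9,
                          iiv = FALSE, iov = FALSE, ruv = FALSE)
  sim <- simulate_cohort(spec, pop_dabohd(), pop_tra())
  obs <- sim$events[sim$events$EVID == 0L, ]
  ind <- apply_covariates(pop_dabohd(), covariates(61.2, 0))
  for (an in c("DAB", "OHD")) {
    o <- obs[obs$ANALYTE == an, ]
    typ <- ss_conc(ind, 150, 12, o$TIME %% 12)[[tolower(substr(an, 1, 3))]]
    expect_equal(o$DV, typ, tolerance = 1e-10)
  }
  # every subject has identical records at matching occasions
  o1 <- obs[obs$ID == "S001", "DV"]
  for (id in c("S002", "S003")) expect_equal(obs[obs$ID == id, "DV"], o1)
})

test_that("median simulated clearance matches the typical value with IIV on", {
  des <- fixed_design(500, n_occ = 1, tra = FALSE)
  spec <- simulation_spec(des$covariates, des$occasions, seed = 10,
                          iiv = TRUE, iov = FALSE, ruv = FALSE)
  sim <- simulate_cohort(spec, pop_dabohd())
  expect_equal(stats::median(sim$truth$cl_dab), 19.3, tolerance = 0.03)
  expect_equal(stats::median(sim$truth$cl_ohd), 23.2, tolerance = 0.03)
})

test_that("simulated event tables validate and round-trip through CSV exactly", {
  des <- fixed_design(3, n_occ = 2)
  spec <- simulation_spec(des$covariates, des$occasions, seed = 11)
  sim <- simulate_cohort(spec, pop_dabohd(), pop_tra())
  expect_silent(validate_event_table(sim$events))
  tf <- withr::local_tempfile(fileext = ".csv")
  write_event_table(sim$events, tf)
  back <- read_event_table(tf)
  for (cl in c("ID", "TIME", "EVID", "ANALYTE", "OCC"))
    expect_equal(back[[cl]], sim$events[[cl]])
  expect_equal(back$DV, sim$events$DV, tolerance = 1e-12)
  # identical seeds reproduce the whole dataset
  sim2 <- simulate_cohort(spec, pop_dabohd(), pop_tra())
  expect_identical(sim$events, sim2$events)
})
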
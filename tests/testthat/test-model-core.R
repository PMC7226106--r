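# Covariate model and structural concentration predictions.

test_that("covariate equations reproduce hand-computed individual clearances", {
  pop <- pop_dabohd()
  # reference man at the centering age: all multipliers are 1
  ref <- apply_covariates(pop, covariates(age = 61.2, sex = 0))
  expect_equal(ref$cl, 19.3)
  expect_equal(ref$clm, 23.2)
  # woman at the centering age: only the sex multiplier acts on CL/F
  w <- apply_covariates(pop, covariates(age = 61.2, sex = 1))
  expect_equal(w$cl, 19.3 * 0.832)
  expect_equal(w$clm, 23.2)
  # young man: hand evaluation of the linear centered age terms
  y <- apply_covariates(pop, covariates(age = 20, sex = 0))
  expect_equal(y$cl, 19.3 * (1 - 0.536 * (20 - 61.2) / 61.2),
               tolerance = 1e-12)
  expect_equal(y$cl, 26.2641, tolerance = 1e-4)
  expect_equal(y$clm, 32.3993, tolerance = 1e-4)
})

test_that("random effects scale parameters lognormally and IOV attaches per occasion", {
  pop <- pop_dabohd()
  re <- random_effects(eta = c(cl = 0.2, v2 = -0.1, clm = 0.3, v3 = 0.05),
                       kappa = c("1" = 0.1, "2" = -0.2))
  ind <- apply_covariates(pop, covariates(61.2, 0), re)
  expect_equal(ind$cl, 19.3 * exp(0.2))
  expect_equal(ind$v2, 39.1 * exp(-0.1))
  expect_equal(ind$v3, 5.11 * exp(0.05))
  expect_equal(unname(ind$cl_by_occ),
               19.3 * exp(0.2) * exp(c(0.1, -0.2)))
  # trametinib: no covariate terms, eta on CL and Q only
  tra <- apply_covariates(pop_tra(), covariates(30, 1),
                          random_effects(eta = c(cl = 0.5, q = -0.5)))
  expect_equal(tra$cl, 5.83 * exp(0.5))
  expect_equal(tra$q, 64.9 * exp(-0.5))
  expect_equal(tra$v2, 61.9)
})

test_that("unsupported ages and invalid inputs are rejected", {
  expect_error(covariates(age = 15, sex = 0), "18-100")
  expect_error(covariates(age = 101, sex = 1), "18-100")
  expect_error(covariates(age = 50, sex = 2), "sex")
  expect_error(pop_dabohd(cl_f = -1), "> 0")
  expect_error(pop_dabohd(ruv_corr = 1.2), "ruv_corr")
})

test_that("no drug appears before the first dose plus lag time", {
  ind <- apply_covariates(pop_dabohd(), covariates(61.2, 0))
  reg <- make_regimen(150, 12, 3)
  pr <- profile_dabohd(ind, reg, c(0, 0.2, 0.49, 0.6, 2))
  expect_equal(pr$dab[1:3], c(0, 0, 0))
  expect_equal(pr$ohd[1:3], c(0, 0, 0))
  expect_gt(pr$dab[4], 0)
  tra <- apply_covariates(pop_tra(), NULL)
  expect_equal(profile_tra(tra, make_regimen(2, 24, 1, drug = "TRA"),
                           c(0, 0.5, 0.7))$tra, c(0, 0, 0))
})

test_that("predictions are homogeneous of degree 1 in dose and non-negative", {
  ind <- apply_covariates(pop_dabohd(), covariates(45, 1))
  tt <- seq(0, 72, by = 1.5)
  p1 <- profile_dabohd(ind, make_regimen(150, 12, 6), tt)
  p2 <- profile_dabohd(ind, make_regimen(300, 12, 6), tt)
  expect_equal(p2$dab, 2 * p1$dab, tolerance = 1e-10)
  expect_equal(p2$ohd, 2 * p1$ohd, tolerance = 1e-10)
  expect_true(all(p1$dab >= 0 & p1$ohd >= 0))
})

test_that("analytic solution matches the stiff ODE oracle and conserves moles", {
  ind <- apply_covariates(pop_dabohd(), covariates(61.2, 0))
  reg <- make_regimen(150, 12, 8)
  tt <- seq(1, 96, by = 1)
  pr <- profile_dabohd(ind, reg, tt)
  ode <- ode_oracle(ind, reg, tt)
  dab_ode <- ode[, "A2"] / ind$v2 * ind$mw_dab
  ohd_ode <- ode[, "A3"] / ind$v3 * ind$mw_ohd
  expect_lt(max(abs(pr$dab - dab_ode)) / max(dab_ode), 1e-8)
  expect_lt(max(abs(pr$ohd - ohd_ode)) / max(ohd_ode), 1e-8)
  # molar mass balance: analytic compartment total + independently
  # integrated eliminated amount = dose administered so far
  X <- dabtrapk:::cpp_profile_states(dabtrapk:::pk_matrix(ind),
                                     reg$time + ind$tlag,
                                     dabtrapk:::dose_to_system_units(reg$amt, ind),
                                     tt)
  dosed <- vapply(tt, function(t)
    sum(dabtrapk:::dose_to_system_units(reg$amt, ind)[reg$time + ind$tlag <= t]),
    numeric(1))
  balance <- rowSums(X) + ode[, "SINK"]
  expect_lt(max(abs(balance - dosed)) / max(dosed), 1e-7)
})

test_that("trametinib single-dose AUC to infinity equals dose over clearance", {
  ind <- apply_covariates(pop_tra(), NULL)
  tt <- seq(0, 2000, by = 0.25)
  pr <- profile_tra(ind, make_regimen(2, 24, 1, drug = "TRA"), tt)
  auc <- dabtrapk:::trapz(tt, pr$tra)
  expect_equal(auc, 2e6 / (ind$cl * 1000), tolerance = 0.005)
})

test_that("steady-state profile reduces to the one-compartment textbook formula", {
  # Q -> 0 decouples the peripheral compartment
  pop <- pop_tra(q_f = 1e-9)
  ind <- apply_covariates(pop, NULL)
  tau <- 24; dose <- 2
  tt <- seq(0, tau, length.out = 49)
  ssp <- steady_state_profile(ind, dose, tau)
  ke <- ind$cl / ind$v2; ka <- ind$ka
  tref <- ssp$time
  te <- pmax(tref - ind$tlag, 0)
  ctext <- dose * 1000 / ind$v2 * ka / (ka - ke) *
    (exp(-ke * te) / (1 - exp(-ke * tau)) -
       exp(-ka * te) / (1 - exp(-ka * tau)))
  # before the lag the textbook interval profile continues the previous dose
  pre <- tref < ind$tlag
  ctext[pre] <- dose * 1000 / ind$v2 * ka / (ka - ke) *
    (exp(-ke * (tref[pre] + tau - ind$tlag)) / (1 - exp(-ke * tau)) -
       exp(-ka * (tref[pre] + tau - ind$tlag)) / (1 - exp(-ka * tau)))
  expect_equal(ssp$tra, ctext, tolerance = 1e-5)
})

test_that("steady-state interval AUC matches the classic equations", {
  ind <- apply_covariates(pop_dabohd(), covariates(61.2, 0))
  ssp <- steady_state_profile(ind, 150, 12, n_grid = 721)
  expect_equal(dabtrapk:::trapz(ssp$time, ssp$dab),
               150e6 / (ind$cl * 1000), tolerance = 0.005)
  expect_equal(dabtrapk:::trapz(ssp$time, ssp$ohd),
               (150 / ind$mw_dab * ind$mw_ohd) * 1e6 / (ind$clm * 1000),
               tolerance = 0.005)
  # closed-form steady state agrees with the superposition construction
  sc <- ss_conc(ind, 150, 12, ssp$time[-length(ssp$time)])
  expect_equal(sc$dab, ssp$dab[-length(ssp$dab)], tolerance = 1e-5)
})

test_that("steady-state accumulation errors out when the cap is reached", {
  # an extremely slow peripheral compartment keeps accumulating past the cap
  pop <- pop_dabohd(q_f = 0.2, v4_f = 5000)
  ind <- apply_covariates(pop, covariates(61.2, 0))
  expect_error(steady_state_profile(ind, 150, 12, max_doses = 50),
               "steady state not reached")
})
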
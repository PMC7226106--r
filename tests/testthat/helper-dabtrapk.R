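# Shared fixtures: independent ODE oracle and small simulated datasets,
# all built in code at test time.

# Independent numerical solution of the compartmental system by a stiff ODE
# integrator (deSolve), with an extra sink state accumulating the
# eliminated amount so molar mass balance can be checked.
ode_oracle <- function(ind, regimen, times, rtol = 1e-11, atol = 1e-11) {
  A <- dabtrapk:::pk_matrix(ind)
  K <- nrow(A)
  kel <- if (ind$model == "dabohd") A[3, 3] + A[5, 3] else A[2, 2] + A[3, 2]
  el_from <- if (ind$model == "dabohd") 3L else 2L
  rhs <- function(t, y, p) {
    dy <- as.numeric(A %*% y[seq_len(K)])
    list(c(dy, -kel * y[el_from]))
  }
  amt <- dabtrapk:::dose_to_system_units(regimen$amt, ind)
  evd <- data.frame(var = "A1", time = regimen$time + ind$tlag,
                    value = amt, method = "add")
  y0 <- stats::setNames(rep(0, K + 1), c(paste0("A", seq_len(K)), "SINK"))
  tt <- sort(unique(c(times, evd$time)))
  out <- deSolve::ode(y0, tt, rhs, NULL, events = list(data = evd),
                      rtol = rtol, atol = atol)
  out[match(times, out[, 1]), , drop = FALSE]
}

# A small fixed-covariate cohort design: n subjects, n_occ occasions with one
# sampling time each, everyone on 150 mg BID + 2 mg QD.
fixed_design <- function(n, n_occ = 2, age = 61.2, sex = 0,
                         tads = c(2, 9), days = c(30, 60, 85),
                         tra = TRUE) {
  cov <- data.frame(id = sprintf("S%03d", seq_len(n)), age = age, sex = sex)
  occ <- do.call(rbind, lapply(cov$id, function(id)
    data.frame(id = id, occ = seq_len(n_occ), day = days[seq_len(n_occ)],
               tad = rep_len(tads, n_occ), dose_dab = 150,
               dose_tra = if (tra) 2 else NA_real_)))
  list(covariates = cov, occasions = occ)
}

# Random parameter draws within +/-50% of the final estimates (structural
# fixed effects only).
draw_pop_dabohd <- function() {
  f <- function(x) x * stats::runif(1, 0.5, 1.5)
  pop_dabohd(cl_f = f(19.3), v2_f = f(39.1), q_f = f(3.40), v4_f = f(18.7),
             clm_f = f(23.2), v3_f = f(5.11), qm_f = f(7.21), v5_f = f(27.1),
             ka = f(1.8), tlag = f(0.499))
}

draw_pop_tra <- function() {
  f <- function(x) x * stats::runif(1, 0.5, 1.5)
  pop_tra(cl_f = f(5.83), v2_f = f(61.9), ka = f(0.913), q_f = f(64.9),
          v3_f = f(417), tlag = f(0.709))
}
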
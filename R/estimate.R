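# Individual (MAP / empirical-Bayes) estimation from sparse concentrations,
# naive-pooled fixed-effect fitting for recovery and bootstrap, and external
# validation metrics (MPE / RMSE).

omega2_vec <- function(pop) cv_to_omega2(iiv_cvs(pop))

# Split a MAP parameter vector into eta / kappa given the template
split_par <- function(par, eta_names, n_occ) {
  eta <- par[seq_along(eta_names)]
  names(eta) <- eta_names
  kappa <- if (n_occ > 0) par[length(eta_names) + seq_len(n_occ)] else numeric(0)
  list(eta = eta, kappa = kappa)
}

#' MAP objective: -2 log posterior kernel for one subject
#'
#' Data term: squared standardized residuals plus `log det` of the residual
#' covariance — proportional error for DAB/OHD, with DAB/OHD observations at
#' the same occasion and time entering as a correlated 2x2 block; additive
#' error for TRA.  Prior term: `sum(eta^2/omega^2)` plus the analogous kappa
#' terms for occasion-specific CL/F.
#'
#' The proportional error SD is anchored at the observed concentration
#' (`g = sigma * y`, floored at 1e-6 ng/mL): the residual weights are then
#' parameter-free, so noise-free data recover the generating parameters
#' exactly instead of carrying the order-`sigma^2` downward bias that
#' prediction-scaled extended-least-squares weighting induces at this
#' residual magnitude (sigma about 0.5).
#'
#' @param par Parameter vector: etas in the order of [iiv_names()] followed
#'   by one kappa per occasion (DAB/OHD model with `estimate_iov = TRUE`).
#' @param data Observation data frame with columns `analyte`, `dose` (mg),
#'   `interval` (h), `tad` (h), `dv` (ng/mL), `occ`.
#' @param pop Population parameter set.
#' @param cov [covariates()] of the subject (NULL for trametinib).
#' @param estimate_iov Include per-occasion kappa parameters (DAB/OHD only).
#' @param ctx Precomputed weighting structure (internal; built from the
#'   data when NULL).
#' @return The scalar objective value.
#' @export
map_objective <- function(par, data, pop, cov = NULL, estimate_iov = TRUE,
                          ctx = NULL) {
  if (is.null(ctx)) ctx <- map_ctx(data, pop, estimate_iov)
  sp <- split_par(par, ctx$en, ctx$n_occ)
  pr <- map_predict(sp, data, pop, cov, ctx$occs)
  obj <- sum(sp$eta^2 / ctx$om2) + ctx$const
  if (ctx$n_occ > 0) obj <- obj + sum(sp$kappa^2 / ctx$om2_iov)
  r <- data$dv - pr
  obj <- obj + sum(ctx$w * r^2)
  for (p in ctx$pairs)
    obj <- obj + p$Sinv[1] * r[p$i_d]^2 + p$Sinv[3] * r[p$i_o]^2 +
      2 * p$Sinv[2] * r[p$i_d] * r[p$i_o]
  obj
}

# Residual-weighting structure of the MAP objective.  The error magnitudes
# are data-anchored (proportional: sigma * observed; additive: constant),
# so the inverse covariances and log-determinant constants can be built
# once per subject.  `w` holds per-observation quadratic weights (zero for
# observations that belong to a correlated DAB/OHD pair); `pairs` holds the
# 2x2 inverse-covariance entries (dd, do, oo) of same-time pairs.
map_ctx <- function(data, pop, estimate_iov = TRUE) {
  en <- iiv_names(pop)
  occs <- sort(unique(data$occ))
  n_occ <- if (inherits(pop, "pop_dabohd") && estimate_iov) length(occs) else 0
  n <- nrow(data)
  ctx <- list(en = en, occs = occs, n_occ = n_occ, om2 = omega2_vec(pop),
              om2_iov = if (n_occ > 0) cv_to_omega2(pop$iov_cl) else NA_real_)
  if (inherits(pop, "pop_tra")) {
    ctx$w <- rep(1 / pop$ruv_add^2, n)
    ctx$pairs <- list()
    ctx$const <- n * log(pop$ruv_add^2)
    return(ctx)
  }
  s <- ifelse(data$analyte == "DAB", pop$ruv_dab, pop$ruv_ohd)
  g <- s * pmax(data$dv, 1e-6)
  rho <- pop$ruv_corr
  w <- 1 / g^2
  const <- 0
  pairs <- list()
  key <- paste(data$occ, signif(data$tad, 10))
  for (k in unique(key)) {
    idx <- which(key == k)
    i_d <- idx[data$analyte[idx] == "DAB"]
    i_o <- idx[data$analyte[idx] == "OHD"]
    if (length(i_d) == 1 && length(i_o) == 1) {
      gd <- g[i_d]; go <- g[i_o]
      det <- gd^2 * go^2 * (1 - rho^2)
      pairs[[length(pairs) + 1L]] <- list(
        i_d = i_d, i_o = i_o,
        Sinv = c(go^2, -rho * gd * go, gd^2) / det)
      w[c(i_d, i_o)] <- 0
      const <- const + log(det)
    } else {
      const <- const + sum(log(g[idx]^2))
    }
  }
  ctx$w <- w; ctx$pairs <- pairs; ctx$const <- const
  ctx
}

# Predictions (ng/mL) for the subject's observation rows given eta/kappa
map_predict <- function(sp, data, pop, cov, occs) {
  re <- random_effects(eta = sp$eta,
                       kappa = if (length(sp$kappa)) {
                         k <- sp$kappa; names(k) <- as.character(occs); k
                       } else numeric(0))
  ind <- apply_covariates(pop, cov, re)
  pred <- numeric(nrow(data))
  grp <- paste(data$occ, data$dose, data$interval)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    ind_g <- ind
    if (!is.null(ind$cl_by_occ)) {
      k <- match(as.character(data$occ[idx[1]]), names(ind$cl_by_occ))
      if (!is.na(k)) ind_g$cl <- unname(ind$cl_by_occ[k])
    }
    P <- ss_conc_mat(ind_g, data$dose[idx[1]], data$interval[idx[1]],
                     data$tad[idx])
    pred[idx] <- if (ind$model == "dabohd")
      ifelse(data$analyte[idx] == "DAB", P[, "dab"], P[, "ohd"])
    else P[, "tra"]
  }
  pred
}

#' MAP (empirical Bayes) fit of one subject's random effects
#'
#' Minimizes [map_objective()] with a quasi-Newton local optimizer from
#' eta = 0 plus four seeded random perturbations; the best objective wins,
#' with ties (within 1e-6) broken by the smallest `||eta||`.  The absorption
#' parameters ka and tlag are never estimated at the individual level.
#'
#' @param data Observation data frame (see [map_objective()]); at least one
#'   row.
#' @param pop Population parameter set.
#' @param cov Subject covariates ([covariates()]; NULL for trametinib).
#' @param estimate_iov Estimate per-occasion kappas (DAB/OHD only).
#' @param n_starts Number of starts (1 = eta 0 only).
#' @param seed Seed for the start perturbations.
#' @return A `map_fit` list: `eta`, `kappa`, `ind` (individual parameters),
#'   `pred`, `objective`, `convergence` (TRUE if any start converged),
#'   `auc` (per-occasion data frame of AUC_DAB/AUC_OHD or AUC_TRA).
#' @export
fit_map <- function(data, pop, cov = NULL, estimate_iov = TRUE,
                    n_starts = 5, seed = 1) {
  if (is.null(data) || nrow(data) == 0)
    stop("MAP estimation needs at least one observation")
  en <- iiv_names(pop)
  occs <- sort(unique(data$occ))
  n_occ <- if (inherits(pop, "pop_dabohd") && estimate_iov) length(occs) else 0
  n_par <- length(en) + n_occ
  om <- sqrt(c(omega2_vec(pop),
               rep(if (n_occ > 0) cv_to_omega2(pop$iov_cl) else 0, n_occ)))
  ctx <- map_ctx(data, pop, estimate_iov)
  obj <- function(p) {
    v <- map_objective(p, data, pop, cov, estimate_iov, ctx)
    if (!is.finite(v)) 1e10 else v   # guard against overflow at wild etas
  }
  starts <- with_seed(seed,
    c(list(rep(0, n_par)),
      lapply(seq_len(max(0, n_starts - 1)),
             function(k) stats::rnorm(n_par, 0, 0.5 * om))))
  fits <- lapply(starts, function(s)
    tryCatch(stats::nlminb(s, obj, lower = rep(-5, n_par),
                           upper = rep(5, n_par)),
             error = function(e) NULL))
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("MAP optimization failed from every start")
  objs <- vapply(fits, function(f) f$objective, numeric(1))
  best <- which(objs <= min(objs) + 1e-6)
  if (length(best) > 1) {
    norms <- vapply(fits[best],
                    function(f) sum(f$par[seq_along(en)]^2), numeric(1))
    best <- best[which.min(norms)]
  } else best <- best[1]
  fit <- fits[[best]]
  sp <- split_par(fit$par, en, n_occ)
  re <- random_effects(eta = sp$eta,
                       kappa = if (n_occ > 0) {
                         k <- sp$kappa; names(k) <- as.character(occs); k
                       } else numeric(0))
  ind <- apply_covariates(pop, cov, re)
  pred <- map_predict(sp, data, pop, cov, occs)
  occ_tab <- unique(data[, c("occ", "dose", "interval")])
  occ_tab <- occ_tab[order(occ_tab$occ), , drop = FALSE]
  auc <- if (inherits(pop, "pop_dabohd")) {
    cl_occ <- if (!is.null(ind$cl_by_occ))
      unname(ind$cl_by_occ[as.character(occ_tab$occ)]) else rep(ind$cl, nrow(occ_tab))
    data.frame(occ = occ_tab$occ, dose = occ_tab$dose,
               auc_dab = auc_interval(occ_tab$dose, cl_occ, "DAB",
                                      pop$mw_dab, pop$mw_ohd),
               auc_ohd = auc_interval(occ_tab$dose, ind$clm, "OHD",
                                      pop$mw_dab, pop$mw_ohd))
  } else {
    data.frame(occ = occ_tab$occ, dose = occ_tab$dose,
               auc_tra = auc_interval(occ_tab$dose, ind$cl, "TRA"))
  }
  structure(list(eta = sp$eta, kappa = sp$kappa, ind = ind, pred = pred,
                 objective = fit$objective,
                 convergence = any(vapply(fits, function(f)
                   f$convergence == 0, logical(1))),
                 auc = auc),
            class = "map_fit")
}

# Expand repeated-dosing rows of an event table into individual dose times
# for one subject and drug, up to t_max.
expand_doses <- function(events, id, drug, t_max) {
  dr <- events[events$EVID == 1L & events$ID == id &
                 events$ANALYTE == drug, , drop = FALSE]
  if (!nrow(dr)) return(NULL)
  dr <- dr[order(dr$TIME), , drop = FALSE]
  ends <- c(dr$TIME[-1], t_max)
  out <- do.call(rbind, lapply(seq_len(nrow(dr)), function(k) {
    tt <- seq(dr$TIME[k], max(dr$TIME[k], ends[k] - 1e-9), by = dr$II[k])
    data.frame(time = tt, amt = dr$AMT[k], drug = drug)
  }))
  structure(out, class = c("regimen", "data.frame"))
}

#' Naive-pooled fixed-effect fit
#'
#' Fits the structural fixed effects (clearances and volumes, on the log
#' scale) with all random effects fixed at zero: log-scale least squares for
#' the proportional-error DAB/OHD model, ordinary least squares for the
#' additive-error TRA model.  The absorption constants ka and tlag are held
#' at their initial values (ka is fixed in the population model; the lag
#' makes the log-scale objective non-smooth).  Used for recovery tests and
#' as the default bootstrap refitter — it stands in for a full mixed-effects
#' likelihood engine, which is out of scope here.
#'
#' @param events Event table (dose and observation rows).
#' @param model `"dabohd"` or `"tra"`.
#' @param init Population parameter set supplying starting values and the
#'   fixed ka/tlag; defaults to the final model.
#' @param jitter Lognormal SD of the random perturbation applied to the
#'   starting values (0 = start at `init`).
#' @param seed Seed for the perturbation.
#' @param steady_state Predict each observation from the steady state of
#'   its current repeated-dose regimen (appropriate for chronic-dosing TDM
#'   data; predictions are cached over identical dose/interval/time-after-
#'   dose combinations across subjects).  FALSE solves each subject's full
#'   dosing history.
#' @return A list with `estimates` (named vector, L/h and L), `objective`,
#'   `convergence`, `non_identifiable` flag.
#' @export
fit_naive_pooled <- function(events, model = c("dabohd", "tra"), init = NULL,
                             jitter = 0.3, seed = 1, steady_state = FALSE) {
  model <- match.arg(model)
  if (is.null(init)) init <- if (model == "dabohd") pop_dabohd() else pop_tra()
  if ("BLQ" %in% names(events)) events <- blq_filter(events)
  pnames <- if (model == "dabohd")
    c("cl_f", "v2_f", "q_f", "v4_f", "clm_f", "v3_f", "qm_f", "v5_f")
  else c("cl_f", "v2_f", "q_f", "v3_f")
  analytes <- if (model == "dabohd") c("DAB", "OHD") else "TRA"
  drug <- if (model == "dabohd") "DAB" else "TRA"
  obs <- events[events$EVID == 0L & events$ANALYTE %in% analytes, , drop = FALSE]
  if (!nrow(obs)) stop("no observations for model ", model)
  ids <- unique(obs$ID)
  # one profile evaluation per unique design (regimen + times)
  designs <- lapply(ids, function(id) {
    o <- obs[obs$ID == id, , drop = FALSE]
    reg <- expand_doses(events, id, drug, max(o$TIME))
    if (is.null(reg)) stop("subject ", id, " has no ", drug, " dose rows")
    list(id = id, reg = reg, times = o$TIME, analyte = o$ANALYTE, dv = o$DV,
         key = paste(paste(reg$time, reg$amt, collapse = ";"),
                     paste(signif(o$TIME, 10), o$ANALYTE, collapse = ";")))
  })
  keys <- vapply(designs, `[[`, character(1), "key")
  uniq <- designs[!duplicated(keys)]
  build_ind <- function(logp) {
    p <- as.list(exp(logp)); names(p) <- pnames
    if (model == "dabohd")
      list(model = "dabohd", cl = p$cl_f, v2 = p$v2_f, ka = init$ka,
           q = p$q_f, v4 = p$v4_f, clm = p$clm_f, v3 = p$v3_f, qm = p$qm_f,
           v5 = p$v5_f, tlag = init$tlag,
           mw_dab = init$mw_dab, mw_ohd = init$mw_ohd)
    else
      list(model = "tra", cl = p$cl_f, v2 = p$v2_f, ka = init$ka,
           q = p$q_f, v3 = p$v3_f, tlag = init$tlag)
  }
  predict_design <- function(ind, d) {
    pr <- if (model == "dabohd") {
      P <- profile_dabohd(ind, d$reg, d$times)
      ifelse(d$analyte == "DAB", P$dab, P$ohd)
    } else profile_tra(ind, d$reg, d$times)$tra
    pr
  }
  resid_fun <- function(logp) {
    ind <- build_ind(logp)
    pred_by_key <- lapply(uniq, function(d) predict_design(ind, d))
    names(pred_by_key) <- vapply(uniq, `[[`, character(1), "key")
    unlist(lapply(designs, function(d) {
      pr <- pred_by_key[[d$key]]
      if (model == "dabohd") {
        ok <- d$dv > 0
        log(pmax(pr[ok], 1e-9)) - log(d$dv[ok])
      } else pr - d$dv
    }), use.names = FALSE)
  }
  if (steady_state) {
    des <- obs_design(events)
    des <- des[des$ANALYTE %in% analytes & !is.na(des$dose), , drop = FALSE]
    skey <- paste(des$dose, des$interval, signif(des$tad, 8))
    sgroups <- lapply(split(seq_len(nrow(des)), skey), function(k) list(
      rows = k, dose = des$dose[k[1]], interval = des$interval[k[1]],
      tad = des$tad[k[1]], is_dab = des$ANALYTE[k] == "DAB"))
    dv_ss <- des$DV
    resid_fun <- function(logp) {
      ind <- build_ind(logp)
      pr <- numeric(nrow(des))
      for (g in sgroups) {
        P <- ss_conc_mat(ind, g$dose, g$interval, g$tad)
        pr[g$rows] <- if (model == "dabohd")
          ifelse(g$is_dab, P[1, "dab"], P[1, "ohd"]) else P[1, "tra"]
      }
      if (model == "dabohd") {
        ok <- dv_ss > 0
        log(pmax(pr[ok], 1e-9)) - log(dv_ss[ok])
      } else pr - dv_ss
    }
  }
  objective <- function(logp) sum(resid_fun(logp)^2)
  start <- log(unlist(init[pnames])) +
    if (jitter > 0) with_seed(seed, stats::rnorm(length(pnames), 0, jitter))
    else 0
  fit <- stats::nlminb(start, objective,
                       lower = log(unlist(init[pnames])) - 5,
                       upper = log(unlist(init[pnames])) + 5)
  # identifiability: numerical Jacobian of residuals at the optimum
  eps <- 1e-5
  r0 <- resid_fun(fit$par)
  J <- vapply(seq_along(fit$par), function(j) {
    pj <- fit$par; pj[j] <- pj[j] + eps
    (resid_fun(pj) - r0) / eps
  }, numeric(length(r0)))
  sv <- svd(J, nu = 0, nv = 0)$d
  est <- exp(fit$par)
  names(est) <- sub("_f$", "", pnames)
  list(estimates = est, objective = fit$objective,
       convergence = fit$convergence == 0,
       non_identifiable = (min(sv) / max(sv)) < 1e-8)
}

#' Bias and precision of model predictions (MPE, RMSE)
#'
#' Relative prediction errors `(pred - obs) / obs`: MPE% is their mean x
#' 100 (bias); RMSE% is the root of the mean squared relative error x 100
#' (precision).  Bootstrap-percentile confidence intervals are attached.
#'
#' @param pred,obs Paired vectors; `obs` must be positive.
#' @param n_boot Bootstrap replicates for the CIs.
#' @param conf Confidence level.
#' @param seed Optional RNG seed.
#' @return A list with `mpe`, `mpe_ci`, `rmse`, `rmse_ci`, `n`.
#' @export
prediction_errors <- function(pred, obs, n_boot = 1000, conf = 0.95,
                              seed = NULL) {
  if (length(pred) != length(obs)) stop("pred and obs must be paired")
  if (!length(pred)) stop("empty input")
  if (any(obs <= 0)) stop("obs must be > 0")
  pe <- (pred - obs) / obs
  mpe <- 100 * mean(pe)
  rmse <- 100 * sqrt(mean(pe^2))
  a <- (1 - conf) / 2
  bs <- with_seed(seed, replicate(n_boot, {
    i <- sample.int(length(pe), replace = TRUE)
    c(100 * mean(pe[i]), 100 * sqrt(mean(pe[i]^2)))
  }))
  list(mpe = mpe,
       mpe_ci = unname(stats::quantile(bs[1, ], c(a, 1 - a))),
       rmse = rmse,
       rmse_ci = unname(stats::quantile(bs[2, ], c(a, 1 - a))),
       n = length(pe))
}
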
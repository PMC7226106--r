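# Population simulation: random-effect and residual-error generation,
# virtual-cohort concentration datasets, and the covariate-impact simulation
# of composite AUC.

#' Draw interindividual and interoccasion random effects
#'
#' Etas are Normal(0, omega^2) on the log scale with `omega^2 = log(1+CV^2)`
#' (the exact lognormal CV mapping), independent across parameters (no
#' off-diagonal IIV correlations are estimated in the model).  Kappas (IOV
#' deviates on CL/F, DAB/OHD model only) are drawn the same way from
#' `iov_cl`, independently per occasion.
#'
#' @param pop A population parameter set.
#' @param n Number of subjects.
#' @param seed Optional RNG seed for reproducibility.
#' @param n_occ Number of occasions per subject (0 = no IOV draws).
#' @param iiv,iov Logical switches; when off the corresponding deviates are
#'   exactly zero.
#' @return A list of class `re_draws` with `eta` (n x parameters matrix) and
#'   `kappa` (n x n_occ matrix or NULL).
#' @export
draw_random_effects <- function(pop, n, seed = NULL, n_occ = 0,
                                iiv = TRUE, iov = TRUE) {
  with_seed(seed, {
  cvs <- iiv_cvs(pop)
  om <- sqrt(cv_to_omega2(cvs))
  eta <- matrix(0, n, length(cvs), dimnames = list(NULL, names(cvs)))
  if (iiv) for (j in seq_along(cvs))
    if (om[j] > 0) eta[, j] <- stats::rnorm(n, 0, om[j])
  kappa <- NULL
  if (n_occ > 0 && inherits(pop, "pop_dabohd")) {
    kappa <- matrix(0, n, n_occ)
    om_iov <- sqrt(cv_to_omega2(pop$iov_cl))
    if (iov && om_iov > 0) kappa[] <- stats::rnorm(n * n_occ, 0, om_iov)
  }
  structure(list(eta = eta, kappa = kappa), class = "re_draws")
  })
}

#' Extract one subject's random effects from a draw set
#' @param draws A `re_draws` object.
#' @param i Subject index.
#' @return A [random_effects()] object.
#' @export
re_for_subject <- function(draws, i) {
  kap <- if (is.null(draws$kappa)) numeric(0) else {
    k <- draws$kappa[i, ]
    names(k) <- as.character(seq_along(k))
    k
  }
  random_effects(eta = draws$eta[i, ], kappa = kap)
}

#' Apply correlated proportional residual error to DAB/OHD predictions
#'
#' Pairs of residuals (eps_DAB, eps_OHD) at the same sampling time are drawn
#' from a bivariate normal with SDs `ruv_dab`, `ruv_ohd` and correlation
#' `ruv_corr`, and applied multiplicatively as `pred * (1 + eps)`.  One pair
#' is drawn per time point even if only one analyte is observed.  Negative
#' simulated values are truncated at 0.
#'
#' @param pred_dab,pred_ohd Predicted concentrations (ng/mL), same length.
#' @param pop A [pop_dabohd()] parameter set.
#' @param seed Optional RNG seed.
#' @return A data frame with columns `dab`, `ohd` of observed values.
#' @export
apply_residual_error <- function(pred_dab, pred_ohd, pop, seed = NULL) {
  stopifnot(length(pred_dab) == length(pred_ohd),
            all(pred_dab >= 0), all(pred_ohd >= 0))
  with_seed(seed, {
    n <- length(pred_dab)
    s1 <- pop$ruv_dab; s2 <- pop$ruv_ohd; rho <- pop$ruv_corr
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    e1 <- s1 * z1
    e2 <- s2 * (rho * z1 + sqrt(max(0, 1 - rho^2)) * z2)
    data.frame(dab = pmax(pred_dab * (1 + e1), 0),
               ohd = pmax(pred_ohd * (1 + e2), 0))
  })
}

#' Apply additive residual error to TRA predictions
#'
#' @param pred Predicted concentrations (ng/mL).
#' @param pop A [pop_tra()] parameter set.
#' @param seed Optional RNG seed.
#' @return Observed values, truncated at 0.
#' @export
apply_residual_error_tra <- function(pred, pop, seed = NULL) {
  stopifnot(all(pred >= 0))
  with_seed(seed,
            pmax(pred + stats::rnorm(length(pred), 0, pop$ruv_add), 0))
}

#' Simulated composite AUC by sex and age under the final covariate model
#'
#' Reproduces the covariate-impact simulation: for each of the four groups
#' (man/woman x age 20/90) draw `n` subjects with lognormal IIV on CL/F and
#' CLm/F, evaluate the covariate model, compute steady-state interval
#' exposures by the classic equations (`AUC_DAB = dose/CL_ind`,
#' `AUC_OHD = molar-corrected dose/CLm_ind`) for dabrafenib 150 mg twice
#' daily, and summarize the composite `AUC_DAB + AUC_OHD`.
#'
#' IOV is a within-subject visit effect and is excluded by default from this
#' single steady-state exposure contrast; it can be switched on.
#'
#' @param pop A [pop_dabohd()] parameter set.
#' @param n Subjects per group.
#' @param seed Optional RNG seed.
#' @param dose Dose (mg) per interval.
#' @param iiv Include IIV (FALSE gives the closed-form typical values).
#' @param iov Include an IOV deviate on CL/F in addition to IIV.
#' @param probs Percentiles for the reported interval.
#' @return A data frame with one row per group: `sex`, `age`, `label`,
#'   `median`, `lower`, `upper` (ng*h/mL).
#' @export
simulate_covariate_impact <- function(pop, n = 1000, seed = NULL, dose = 150,
                             iiv = TRUE, iov = FALSE,
                             probs = c(0.025, 0.975)) {
  with_seed(seed, {
  grid <- expand.grid(sex = c(0L, 1L), age = c(20, 90))
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    cov <- covariates(age = grid$age[g], sex = grid$sex[g])
    om_cl <- sqrt(cv_to_omega2(pop$iiv_cl))
    om_clm <- sqrt(cv_to_omega2(pop$iiv_clm))
    eta_cl <- if (iiv) stats::rnorm(n, 0, om_cl) else numeric(n)
    eta_clm <- if (iiv) stats::rnorm(n, 0, om_clm) else numeric(n)
    if (iov) {
      om_iov <- sqrt(cv_to_omega2(pop$iov_cl))
      eta_cl <- eta_cl + stats::rnorm(n, 0, om_iov)
    }
    typ <- apply_covariates(pop, cov)
    cl <- typ$cl * exp(eta_cl)
    clm <- typ$clm * exp(eta_clm)
    comp <- auc_interval(dose, cl, "DAB", pop$mw_dab, pop$mw_ohd) +
      auc_interval(dose, clm, "OHD", pop$mw_dab, pop$mw_ohd)
    qs <- stats::quantile(comp, probs)
    data.frame(sex = grid$sex[g], age = grid$age[g],
               label = paste0(ifelse(grid$sex[g] == 0, "man", "woman"),
                              " ", grid$age[g]),
               median = stats::median(comp), lower = qs[1], upper = qs[2])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  attr(out, "n") <- n
  out
  })
}

#' Specification of a virtual-cohort simulation
#'
#' Bundles the inputs of [simulate_cohort()]: per-subject covariates, the
#' per-occasion sampling design with current doses, and the variability
#' switches.
#'
#' @param covariates Data frame with one row per subject: `id`, `age`, `sex`
#'   (additional baseline columns are carried through).
#' @param occasions Data frame with one row per subject-occasion: `id`,
#'   `occ`, `day` (days since treatment start), `tad` (h after dose at
#'   sampling), `dose_dab` (mg per 12 h) and optionally `dose_tra` (mg per
#'   24 h; NA = not treated with TRA at that occasion).
#' @param seed RNG seed; mandatory so every simulated dataset is
#'   reproducible.
#' @param iiv,iov,ruv Independent switches for the three variability levels.
#' @param interval_dab,interval_tra Dosing intervals (h).
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(covariates, occasions, seed,
                            iiv = TRUE, iov = TRUE, ruv = TRUE,
                            interval_dab = 12, interval_tra = 24) {
  stopifnot(is.data.frame(covariates), nrow(covariates) >= 1,
            all(c("id", "age", "sex") %in% names(covariates)),
            is.data.frame(occasions), nrow(occasions) >= 1,
            all(c("id", "occ", "day", "tad", "dose_dab") %in% names(occasions)))
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  structure(list(covariates = covariates, occasions = occasions, seed = seed,
                 iiv = iiv, iov = iov, ruv = ruv,
                 interval_dab = interval_dab, interval_tra = interval_tra),
            class = "simulation_spec")
}

#' Simulate a virtual cohort's concentration dataset
#'
#' Composes the covariate model, random effects, steady-state predictions at
#' the sampling design, and residual error into an event table
#' (dose + observation rows, see [write_event_table()]), with the true
#' individual parameters and true per-occasion AUCs retained in a `truth`
#' side table for recovery experiments.
#'
#' Samples are taken at steady state (all patients are on chronic twice- or
#' once-daily dosing); the occasion-specific CL/F (IOV) applies to both the
#' simulated concentrations and the true occasion AUCs.
#'
#' @param spec A [simulation_spec()].
#' @param pop_dabohd A [pop_dabohd()] parameter set.
#' @param pop_tra Optional [pop_tra()] parameter set (omit to simulate
#'   DAB/OHD only).
#' @return A list with `events` (event table data frame) and `truth`
#'   (per-occasion data frame of true clearances and AUCs).
#' @export
simulate_cohort <- function(spec, pop_dabohd, pop_tra = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(spec$seed, {
  cov <- spec$covariates
  occ <- spec$occasions
  n <- nrow(cov)
  n_occ_max <- max(table(occ$id))
  dr <- draw_random_effects(pop_dabohd, n, n_occ = n_occ_max,
                            iiv = spec$iiv, iov = spec$iov)
  dr_tra <- if (!is.null(pop_tra))
    draw_random_effects(pop_tra, n, iiv = spec$iiv) else NULL

  ev_rows <- list(); truth_rows <- list()
  for (i in seq_len(n)) {
    id <- cov$id[i]
    ci <- covariates(age = cov$age[i], sex = cov$sex[i])
    occ_i <- occ[occ$id == id, , drop = FALSE]
    occ_i <- occ_i[order(occ_i$day), , drop = FALSE]
    re_i <- re_for_subject(dr, i)
    ind <- apply_covariates(pop_dabohd, ci, re_i)
    ind_tra <- if (!is.null(dr_tra))
      apply_covariates(pop_tra, ci, re_for_subject(dr_tra, i)) else NULL

    # dose rows: one per dose level segment (repeated dosing at interval II)
    dose_seg <- function(drug, amt, t0, ii)
      data.frame(ID = id, TIME = t0, EVID = 1L, AMT = amt, II = ii,
                 DV = NA_real_, ANALYTE = drug, OCC = NA_integer_)
    segs <- list()
    seg_changes <- c(TRUE, diff(occ_i$dose_dab) != 0)
    for (k in which(seg_changes))
      segs[[length(segs) + 1L]] <-
        dose_seg("DAB", occ_i$dose_dab[k],
                 if (k == 1) 0 else occ_i$day[k] * 24, spec$interval_dab)
    has_tra <- !is.null(ind_tra) && "dose_tra" %in% names(occ_i) &&
      any(!is.na(occ_i$dose_tra))
    if (has_tra) {
      tra_occ <- occ_i[!is.na(occ_i$dose_tra), , drop = FALSE]
      seg_tra <- c(TRUE, diff(tra_occ$dose_tra) != 0)
      for (k in which(seg_tra))
        segs[[length(segs) + 1L]] <-
          dose_seg("TRA", tra_occ$dose_tra[k],
                   if (k == 1) 0 else tra_occ$day[k] * 24, spec$interval_tra)
    }

    for (k in seq_len(nrow(occ_i))) {
      occ_k <- occ_i$occ[k]
      ind_k <- ind
      if (!is.null(ind$cl_by_occ) && k <= length(ind$cl_by_occ))
        ind_k$cl <- unname(ind$cl_by_occ[k])
      pred <- ss_conc_mat(ind_k, occ_i$dose_dab[k], spec$interval_dab,
                          occ_i$tad[k])
      obs <- if (spec$ruv)
        apply_residual_error(pred[, "dab"], pred[, "ohd"], pop_dabohd)
      else data.frame(dab = pred[, "dab"], ohd = pred[, "ohd"])
      t_obs <- occ_i$day[k] * 24 + occ_i$tad[k]
      ev_rows[[length(ev_rows) + 1L]] <- data.frame(
        ID = id, TIME = t_obs, EVID = 0L, AMT = NA_real_, II = NA_real_,
        DV = c(obs$dab, obs$ohd), ANALYTE = c("DAB", "OHD"), OCC = occ_k)
      auc_d <- auc_interval(occ_i$dose_dab[k], ind_k$cl, "DAB",
                            pop_dabohd$mw_dab, pop_dabohd$mw_ohd)
      auc_o <- auc_interval(occ_i$dose_dab[k], ind$clm, "OHD",
                            pop_dabohd$mw_dab, pop_dabohd$mw_ohd)
      auc_t <- NA_real_
      if (has_tra && !is.na(occ_i$dose_tra[k])) {
        pred_t <- ss_conc_mat(ind_tra, occ_i$dose_tra[k], spec$interval_tra,
                              occ_i$tad[k])
        dv_t <- if (spec$ruv)
          apply_residual_error_tra(pred_t[, "tra"], pop_tra)
        else pred_t[, "tra"]
        ev_rows[[length(ev_rows) + 1L]] <- data.frame(
          ID = id, TIME = t_obs, EVID = 0L, AMT = NA_real_, II = NA_real_,
          DV = dv_t, ANALYTE = "TRA", OCC = occ_k)
        auc_t <- auc_interval(occ_i$dose_tra[k], ind_tra$cl, "TRA")
      }
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        id = id, occ = occ_k, day = occ_i$day[k],
        dose_dab = occ_i$dose_dab[k],
        cl_dab = ind_k$cl, cl_ohd = ind$clm,
        cl_tra = if (has_tra) ind_tra$cl else NA_real_,
        auc_dab = auc_d, auc_ohd = auc_o, auc_tra = auc_t)
    }
    ev_rows <- c(ev_rows, segs)
  }
  ev <- do.call(rbind, ev_rows)
  ev <- merge(ev, cov, by.x = "ID", by.y = "id", sort = FALSE)
  names(ev)[names(ev) == "age"] <- "AGE"
  names(ev)[names(ev) == "sex"] <- "SEX"
  ev <- ev[order(ev$ID, ev$TIME, ev$EVID == 0), , drop = FALSE]
  rownames(ev) <- NULL
  truth <- do.call(rbind, truth_rows)
  truth$eta_cl <- dr$eta[match(truth$id, cov$id), "cl"]
  truth$eta_clm <- dr$eta[match(truth$id, cov$id), "clm"]
  attr(ev, "seed") <- spec$seed
  list(events = ev, truth = truth)
  })
}
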
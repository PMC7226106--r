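# Synthetic-cohort generator: virtual patients with the covariate,
# regimen, sampling and outcome structure the analysis pipeline assumes.
# Covariate marginals emulate the study cohort; the outcome links (logistic
# dose-limiting-toxicity model, exponential proportional-hazards survival)
# are explicit assumptions recorded in the output metadata — the study
# motivates their signs, not their magnitudes.

#' Specification of a synthetic cohort
#'
#' Defaults reproduce the study conditions: melanoma patients on dabrafenib
#' 150 mg twice daily plus trametinib 2 mg once daily, median age 61.2
#' (range 20-90), 41% women, 13% ECOG PS >= 2, 60% cerebral metastases,
#' 52% with >= 3 metastatic sites, 25% LDH >= 1.5N, 78% on proton-pump
#' inhibitors; 1-3 sampling occasions in the first 90 days (median 2); a
#' DLT probability rising with dabrafenib exposure calibrated to a 23%
#' marginal rate at the typical exposure, onset around day 110, followed by
#' dose reduction; and exponential survival with proportional-hazard
#' effects of ECOG PS >= 2 and metabolic ratio >= 1 (overall survival) and
#' of >= 3 metastatic sites and cerebral metastases (progression-free
#' survival).
#'
#' @param n Number of patients.
#' @param seed RNG seed (mandatory).
#' @param age_meanlog,age_sdlog,age_range Lognormal age distribution,
#'   truncated to the range by resampling.
#' @param p_female,p_ecog_ge2,p_cerebral,p_sites_ge3,p_ldh_ge15,p_ppi
#'   Marginal probabilities of the categorical covariates.
#' @param weight_median,bmi_median Medians of the lognormal weight/BMI.
#' @param dose_dab,dose_tra Starting doses (mg) per 12 h / per 24 h.
#' @param reduced_dose_dab,reduced_dose_tra Doses after a DLT (mg).
#' @param n_occ_probs Probabilities of 1, 2, 3 sampling occasions.
#' @param occ_day_range Days after start within which occasions fall.
#' @param tad_range Sampling time after dose (h).
#' @param dlt_slope Logistic slope per 1000 ng*h/mL of AUC_DAB.
#' @param dlt_rate Target marginal DLT probability at the typical exposure
#'   (sets the intercept `qlogis(dlt_rate) - dlt_slope * 7.772`).
#' @param dlt_onset_median,dlt_onset_range Onset-day distribution (days).
#' @param p_dlt_tra Marginal trametinib DLT probability (no exposure link).
#' @param os_median,pfs_median Baseline exponential survival medians
#'   (months).
#' @param log_hr_os,log_hr_pfs Named log hazard ratios applied to the
#'   corresponding 0/1 covariates.
#' @param horizon Administrative censoring (months).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n = 52, seed,
                        age_meanlog = log(61.2), age_sdlog = 0.25,
                        age_range = c(20, 90),
                        p_female = 0.41, weight_median = 73,
                        bmi_median = 25.9,
                        p_ecog_ge2 = 0.13, p_cerebral = 0.60,
                        p_sites_ge3 = 0.52, p_ldh_ge15 = 0.25, p_ppi = 0.78,
                        dose_dab = 150, dose_tra = 2,
                        reduced_dose_dab = 75, reduced_dose_tra = 1,
                        n_occ_probs = c(0.25, 0.50, 0.25),
                        occ_day_range = c(14, 90), tad_range = c(1, 11.5),
                        dlt_slope = 0.8, dlt_rate = 0.23,
                        dlt_onset_median = 110, dlt_onset_range = c(13, 344),
                        p_dlt_tra = 0.33,
                        os_median = 13.4, pfs_median = 7.0,
                        log_hr_os = c(ecog_ge2 = log(3), ratio_ge_1 = log(2.5)),
                        log_hr_pfs = c(sites_ge3 = log(2.5),
                                       cerebral_mets = log(2)),
                        horizon = 36) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  probs <- c(p_female, p_ecog_ge2, p_cerebral, p_sites_ge3, p_ldh_ge15,
             p_ppi, dlt_rate, p_dlt_tra, n_occ_probs)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (abs(sum(n_occ_probs) - 1) > 1e-8)
    stop("n_occ_probs must sum to 1")
  if (n < 1) stop("n must be >= 1")
  spec <- as.list(environment())
  spec$dlt_intercept <- stats::qlogis(dlt_rate) - dlt_slope * 7.772
  structure(spec, class = "cohort_spec")
}

rlnorm_trunc <- function(n, meanlog, sdlog, range) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(2 * n, meanlog, sdlog)
    out <- c(out, x[x >= range[1] & x <= range[2]])
  }
  out[seq_len(n)]
}

#' Generate a synthetic cohort: covariates and sampling design
#'
#' Deterministic under the spec's seed.  Ages are drawn from the truncated
#' lognormal; categorical covariates are independent Bernoulli draws with
#' the spec's marginals; each patient receives 1-3 sampling occasions at
#' random days within the window, all at the starting doses (reductions are
#' applied after outcome generation with [apply_dose_reductions()]).
#'
#' @param spec A [cohort_spec()].
#' @return A list with `covariates` (one row per patient) and `occasions`
#'   (one row per patient-occasion: `id`, `occ`, `day`, `tad`, `dose_dab`,
#'   `dose_tra`), plus the spec.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
  n <- spec$n
  id <- sprintf("S%04d", seq_len(n))
  ecog_ge2 <- stats::rbinom(n, 1, spec$p_ecog_ge2)
  sites_ge3 <- stats::rbinom(n, 1, spec$p_sites_ge3)
  ldh_ge15 <- stats::rbinom(n, 1, spec$p_ldh_ge15)
  cov <- data.frame(
    id = id,
    age = round(rlnorm_trunc(n, spec$age_meanlog, spec$age_sdlog,
                             spec$age_range), 1),
    sex = stats::rbinom(n, 1, spec$p_female),
    weight = round(stats::rlnorm(n, log(spec$weight_median), 0.20), 1),
    bmi = round(stats::rlnorm(n, log(spec$bmi_median), 0.15), 1),
    ecog_ps = ifelse(ecog_ge2 == 1, 2L + stats::rbinom(n, 1, 0.3),
                     stats::rbinom(n, 1, 0.35)),
    ldh_ratio = round(ifelse(ldh_ge15 == 1, stats::runif(n, 1.5, 4),
                             stats::runif(n, 0.3, 1.45)), 2),
    ppi = stats::rbinom(n, 1, spec$p_ppi),
    n_met_sites = ifelse(sites_ge3 == 1, 3L + stats::rpois(n, 1),
                         1L + stats::rbinom(n, 1, 0.5)),
    cerebral_mets = stats::rbinom(n, 1, spec$p_cerebral))
  n_occ <- sample(1:3, n, replace = TRUE, prob = spec$n_occ_probs)
  occ_rows <- lapply(seq_len(n), function(i) {
    days <- sort(round(stats::runif(n_occ[i], spec$occ_day_range[1],
                                    spec$occ_day_range[2])))
    days <- days + seq_along(days) - 1  # avoid coincident occasions
    data.frame(id = id[i], occ = seq_len(n_occ[i]), day = days,
               tad = round(stats::runif(n_occ[i], spec$tad_range[1],
                                        spec$tad_range[2]), 2),
               dose_dab = spec$dose_dab, dose_tra = spec$dose_tra)
  })
  list(spec = spec, covariates = cov, occasions = do.call(rbind, occ_rows))
  })
}

#' Generate synthetic toxicity and survival outcomes
#'
#' The DLT flag is Bernoulli with probability
#' `plogis(intercept + slope * AUC_DAB / 1000)` using each patient's mean
#' dabrafenib AUC; onset day is lognormal around the spec's median,
#' truncated to its range.  Survival times are exponential with
#' proportional-hazards effects of the spec's named covariates, censored at
#' the administrative horizon.  The link parameters are assumptions and are
#' recorded in the `links` attribute.
#'
#' @param cohort Output of [generate_cohort()].
#' @param exposures Per-occasion exposure table (`id`, `day`, `auc_dab`,
#'   `auc_ohd`, ...), e.g. truth exposures from [simulate_cohort()] passed
#'   through [exposure_summary()].
#' @param spec The [cohort_spec()] (defaults to `cohort$spec`).
#' @return Per-patient outcome data frame: DLT flags and onset days,
#'   `os_months`/`os_event`, `pfs_months`/`pfs_event`, the dichotomized
#'   covariates, and `ratio_ge_1` from the exposure table.
#' @export
generate_outcomes <- function(cohort, exposures, spec = cohort$spec) {
  with_seed(spec$seed + 1L, {
  cov <- code_covariates(cohort$covariates)
  n <- nrow(cov)
  mean_auc <- tapply(exposures$auc_dab, exposures$id, mean)
  mean_ohd <- tapply(exposures$auc_ohd, exposures$id, mean)
  auc <- as.numeric(mean_auc[cov$id])
  ratio_ge_1 <- as.integer((as.numeric(mean_ohd[cov$id]) / auc) >= 1)
  p_dlt <- stats::plogis(spec$dlt_intercept + spec$dlt_slope * auc / 1000)
  dlt_dab <- stats::rbinom(n, 1, p_dlt)
  onset <- function(k) {
    d <- round(stats::rlnorm(k, log(spec$dlt_onset_median), 0.5))
    pmin(pmax(d, spec$dlt_onset_range[1]), spec$dlt_onset_range[2])
  }
  dlt_dab_day <- ifelse(dlt_dab == 1, onset(n), NA_real_)
  dlt_tra <- stats::rbinom(n, 1, spec$p_dlt_tra)
  dlt_tra_day <- ifelse(dlt_tra == 1, onset(n), NA_real_)
  lp <- function(log_hr) {
    v <- numeric(n)
    for (nm in names(log_hr)) {
      x <- if (nm == "ratio_ge_1") ratio_ge_1 else cov[[nm]]
      v <- v + log_hr[[nm]] * x
    }
    v
  }
  draw_surv <- function(median_m, log_hr) {
    rate <- log(2) / median_m * exp(lp(log_hr))
    t <- stats::rexp(n, rate)
    data.frame(months = pmin(t, spec$horizon),
               event = as.integer(t <= spec$horizon))
  }
  os <- draw_surv(spec$os_median, spec$log_hr_os)
  pfs <- draw_surv(spec$pfs_median, spec$log_hr_pfs)
  out <- data.frame(id = cov$id,
                    dlt_dab = dlt_dab, dlt_dab_day = dlt_dab_day,
                    dlt_tra = dlt_tra, dlt_tra_day = dlt_tra_day,
                    os_months = os$months, os_event = os$event,
                    pfs_months = pfs$months, pfs_event = pfs$event,
                    sex = cov$sex, age = cov$age, bmi = cov$bmi,
                    ecog_ge2 = cov$ecog_ge2, sites_ge3 = cov$sites_ge3,
                    ldh_ge15 = cov$ldh_ge15, ppi = cov$ppi,
                    cerebral_mets = cov$cerebral_mets,
                    ratio_ge_1 = ratio_ge_1)
  attr(out, "links") <- list(
    note = "synthetic outcome links; parameters are assumptions",
    dlt = c(intercept = spec$dlt_intercept, slope_per_1000 = spec$dlt_slope),
    os = spec$log_hr_os, pfs = spec$log_hr_pfs,
    baseline_medians = c(os = spec$os_median, pfs = spec$pfs_median),
    horizon = spec$horizon, seed = spec$seed)
  out
  })
}

#' Apply post-DLT dose reductions to the sampling design
#'
#' Occasions after a patient's dabrafenib DLT onset switch to the reduced
#' doses of the spec.
#'
#' @param occasions Occasion table from [generate_cohort()].
#' @param outcomes Outcome table from [generate_outcomes()].
#' @param spec The [cohort_spec()].
#' @return The occasion table with updated `dose_dab` / `dose_tra`.
#' @export
apply_dose_reductions <- function(occasions, outcomes, spec) {
  m <- match(occasions$id, outcomes$id)
  red <- outcomes$dlt_dab[m] == 1 & !is.na(outcomes$dlt_dab_day[m]) &
    occasions$day > outcomes$dlt_dab_day[m]
  occasions$dose_dab[red] <- spec$reduced_dose_dab
  if ("dose_tra" %in% names(occasions))
    occasions$dose_tra[red] <- spec$reduced_dose_tra
  occasions
}
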
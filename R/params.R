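# Population parameter sets, covariates, random effects, and the covariate
# model mapping population to individual parameters.

#' Molecular weights of dabrafenib and hydroxy-dabrafenib
#'
#' Used to carry amounts in molar units through the parent-metabolite system
#' (the complete-conversion mass balance is only exact in moles) and to
#' convert molar concentrations back to ng/mL.
#' @format Numeric scalars, g/mol.
#' @keywords internal
MW_DAB <- 519.56
MW_OHD <- 535.56

#' Final population parameters of the dabrafenib/hydroxy-dabrafenib model
#'
#' Constructs the parameter set of the joint two-compartment parent plus
#' two-compartment metabolite model with first-order absorption, lag time,
#' and complete conversion of dabrafenib (DAB) to hydroxy-dabrafenib (OHD).
#' Defaults are the final-model estimates: typical apparent clearances and
#' volumes, linear centered age effects on both clearances, a proportional
#' sex effect on CL/F, lognormal interindividual variability (IIV) on CL/F,
#' V2/F, CLm/F and V3/F, interoccasion variability (IOV) on CL/F, and a
#' correlated proportional residual error for the two analytes.
#'
#' @param cl_f Typical DAB apparent clearance (L/h).
#' @param v2_f Typical DAB central volume (L).
#' @param ka First-order absorption rate constant (1/h), fixed.
#' @param q_f DAB intercompartmental clearance (L/h).
#' @param v4_f DAB peripheral volume (L).
#' @param clm_f Typical OHD apparent clearance (L/h).
#' @param v3_f OHD central volume (L).
#' @param qm_f OHD intercompartmental clearance (L/h).
#' @param v5_f OHD peripheral volume (L).
#' @param tlag Absorption lag time (h).
#' @param theta_age_cl,theta_age_clm Linear centered age coefficients on
#'   CL/F and CLm/F (dimensionless).
#' @param theta_sex_cl Multiplicative sex effect on CL/F (women vs men).
#' @param m_age Centering age (years), the cohort median.
#' @param iiv_cl,iiv_v2,iiv_clm,iiv_v3 IIV coefficients of variation
#'   (fractions, e.g. 0.160 for 16%).
#' @param iov_cl IOV coefficient of variation on CL/F (fraction).
#' @param ruv_dab,ruv_ohd Proportional residual error CVs (fractions).
#' @param ruv_corr Correlation between the DAB and OHD residual components.
#' @param mw_dab,mw_ohd Molecular weights (g/mol).
#' @return An object of class `c("pop_dabohd", "pop_params")`.
#' @examples
#' pop <- pop_dabohd()
#' pop$cl_f
#' @export
pop_dabohd <- function(cl_f = 19.3, v2_f = 39.1, ka = 1.8, q_f = 3.40,
                       v4_f = 18.7, clm_f = 23.2, v3_f = 5.11, qm_f = 7.21,
                       v5_f = 27.1, tlag = 0.499,
                       theta_age_cl = -0.536, theta_age_clm = -0.589,
                       theta_sex_cl = 0.832, m_age = 61.2,
                       iiv_cl = 0.160, iiv_v2 = 0.508, iiv_clm = 0.240,
                       iiv_v3 = 0.475, iov_cl = 0.174,
                       ruv_dab = 0.487, ruv_ohd = 0.531, ruv_corr = 0.870,
                       mw_dab = MW_DAB, mw_ohd = MW_OHD) {
  p <- list(cl_f = cl_f, v2_f = v2_f, ka = ka, q_f = q_f, v4_f = v4_f,
            clm_f = clm_f, v3_f = v3_f, qm_f = qm_f, v5_f = v5_f,
            tlag = tlag, theta_age_cl = theta_age_cl,
            theta_age_clm = theta_age_clm, theta_sex_cl = theta_sex_cl,
            m_age = m_age, iiv_cl = iiv_cl, iiv_v2 = iiv_v2,
            iiv_clm = iiv_clm, iiv_v3 = iiv_v3, iov_cl = iov_cl,
            ruv_dab = ruv_dab, ruv_ohd = ruv_ohd, ruv_corr = ruv_corr,
            mw_dab = mw_dab, mw_ohd = mw_ohd)
  structural <- c("cl_f", "v2_f", "ka", "q_f", "v4_f", "clm_f", "v3_f",
                  "qm_f", "v5_f", "tlag")
  if (any(unlist(p[structural]) <= 0))
    stop("all structural parameters (clearances, volumes, ka, tlag) must be > 0")
  if (abs(ruv_corr) > 1) stop("|ruv_corr| must be <= 1")
  if (any(c(iiv_cl, iiv_v2, iiv_clm, iiv_v3, iov_cl,
            ruv_dab, ruv_ohd) < 0))
    stop("variability components must be >= 0")
  class(p) <- c("pop_dabohd", "pop_params")
  p
}

#' Final population parameters of the trametinib model
#'
#' Two-compartment model with first-order absorption, lag time and
#' first-order elimination; lognormal IIV on CL/F and Q/F; additive residual
#' error.  No covariate effects were retained for trametinib.
#'
#' @param cl_f Typical apparent clearance (L/h).
#' @param v2_f Central volume (L).
#' @param ka Absorption rate constant (1/h).
#' @param q_f Intercompartmental clearance (L/h).
#' @param v3_f Peripheral volume (L).
#' @param tlag Absorption lag time (h).
#' @param iiv_cl,iiv_q IIV coefficients of variation (fractions).
#' @param ruv_add Additive residual error SD (ng/mL).
#' @return An object of class `c("pop_tra", "pop_params")`.
#' @export
pop_tra <- function(cl_f = 5.83, v2_f = 61.9, ka = 0.913, q_f = 64.9,
                    v3_f = 417.0, tlag = 0.709,
                    iiv_cl = 0.296, iiv_q = 0.802, ruv_add = 4.14) {
  p <- list(cl_f = cl_f, v2_f = v2_f, ka = ka, q_f = q_f, v3_f = v3_f,
            tlag = tlag, iiv_cl = iiv_cl, iiv_q = iiv_q, ruv_add = ruv_add)
  if (any(unlist(p) <= 0, na.rm = TRUE) &&
      any(unlist(p[c("cl_f", "v2_f", "ka", "q_f", "v3_f", "tlag")]) <= 0))
    stop("all structural parameters must be > 0")
  if (iiv_cl < 0 || iiv_q < 0 || ruv_add < 0)
    stop("variability components must be >= 0")
  class(p) <- c("pop_tra", "pop_params")
  p
}

#' Read population parameter sets from a YAML configuration file
#'
#' The file holds one block per drug model (`dabohd`, `tra`) whose keys match
#' the arguments of [pop_dabohd()] and [pop_tra()].  The package ships the
#' final-model estimates in `inst/extdata/popparams.yaml`.
#'
#' @param path Path to the YAML file; defaults to the shipped configuration.
#' @return A list with elements `dabohd` and/or `tra`.
#' @export
read_pop_params <- function(path = system.file("extdata", "popparams.yaml",
                                               package = "dabtrapk")) {
  cfg <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(cfg$dabohd)) out$dabohd <- do.call(pop_dabohd, cfg$dabohd)
  if (!is.null(cfg$tra)) out$tra <- do.call(pop_tra, cfg$tra)
  out
}

#' Patient covariates
#'
#' Age and sex drive the dabrafenib covariate model; the remaining baseline
#' fields are carried along for the exposure-response stage.
#'
#' @param age Age in years; the covariate model is supported for 18-100.
#' @param sex 0 = man, 1 = woman.
#' @param weight,bmi,ecog_ps,ldh_ratio,ppi,n_met_sites,cerebral_mets Optional
#'   baseline fields (kg, kg/m2, ECOG grade, LDH as multiple of the upper
#'   normal limit, 0/1 proton-pump-inhibitor intake, count, 0/1).
#' @return A `covariates` list.
#' @export
covariates <- function(age, sex, weight = NA_real_, bmi = NA_real_,
                       ecog_ps = NA_integer_, ldh_ratio = NA_real_,
                       ppi = NA_integer_, n_met_sites = NA_integer_,
                       cerebral_mets = NA_integer_) {
  if (!is.numeric(age) || length(age) != 1L || is.na(age))
    stop("age must be a single number")
  if (age < 18 || age > 100)
    stop("age ", age, " outside the supported range 18-100 years")
  if (!sex %in% c(0, 1)) stop("sex must be 0 (man) or 1 (woman)")
  structure(list(age = age, sex = sex, weight = weight, bmi = bmi,
                 ecog_ps = ecog_ps, ldh_ratio = ldh_ratio, ppi = ppi,
                 n_met_sites = n_met_sites, cerebral_mets = cerebral_mets),
            class = "covariates")
}

#' Random effects for one subject
#'
#' `eta` holds the lognormal IIV deviates aligned to the model's IIV
#' parameters (`cl`, `v2`, `clm`, `v3` for the DAB/OHD model; `cl`, `q` for
#' trametinib); `kappa` holds per-occasion IOV deviates for CL/F (DAB/OHD
#' model only), named by occasion id.  A zero vector is the typical subject.
#'
#' @param eta Named numeric vector of IIV deviates (missing names are 0).
#' @param kappa Named numeric vector of per-occasion IOV deviates.
#' @return A `random_effects` list.
#' @export
random_effects <- function(eta = numeric(0), kappa = numeric(0)) {
  if (length(eta) && (is.null(names(eta)) || any(!nzchar(names(eta)))))
    stop("eta must be a named vector")
  if (any(!is.finite(eta)) || any(!is.finite(kappa)))
    stop("random effects must be finite")
  structure(list(eta = eta, kappa = kappa), class = "random_effects")
}

eta_of <- function(re, name) {
  if (is.null(re) || !length(re$eta) || !name %in% names(re$eta)) 0
  else unname(re$eta[[name]])
}

#' Apply the covariate and random-effect model
#'
#' Maps population parameters to individual parameters.  For the DAB/OHD
#' model the individual clearances follow the final-model equations
#' \deqn{CL_{ind}/F = CL/F \times (1 + \theta_{age} (AGE - MAGE)/MAGE)
#'   \times \theta_{sex}^{Sex} \times e^{\eta_{CL}}}
#' \deqn{CLm_{ind}/F = CLm/F \times (1 + \theta_{age,m} (AGE - MAGE)/MAGE)
#'   \times e^{\eta_{CLm}}}
#' with Sex = 0/1 for man/woman; V2/F and V3/F are scaled by `exp(eta)`.
#' When IOV deviates are supplied, occasion-specific clearances
#' `CL_ind * exp(kappa_occ)` are attached.  The trametinib model has no
#' covariate terms: only `exp(eta)` on CL/F and Q/F.
#'
#' The linear age multiplier is floored at 0.05 so that extrapolation can
#' never produce a non-positive clearance; ages outside 18-100 are rejected
#' at covariate construction.
#'
#' @param pop A [pop_dabohd()] or [pop_tra()] parameter set.
#' @param cov A [covariates()] object (ignored for trametinib, may be NULL).
#' @param re A [random_effects()] object; NULL means the typical subject.
#' @return An `individual_params` list with fields `cl`, `v2`, `ka`, `q`,
#'   ..., `tlag`, the model tag, and `cl_by_occ` when IOV is present.
#' @examples
#' pop <- pop_dabohd()
#' apply_covariates(pop, covariates(age = 61.2, sex = 1))$cl  # 19.3 * 0.832
#' @export
apply_covariates <- function(pop, cov = NULL, re = NULL) {
  UseMethod("apply_covariates")
}

age_multiplier <- function(theta, age, m_age, floor = 0.05) {
  m <- 1 + theta * (age - m_age) / m_age
  if (m <= 0) {
    m <- floor
    warning("age multiplier floored at ", floor, " for age ", age)
  }
  m
}

#' @export
apply_covariates.pop_dabohd <- function(pop, cov = NULL, re = NULL) {
  if (is.null(cov)) cov <- covariates(age = pop$m_age, sex = 0)
  stopifnot(inherits(cov, "covariates"))
  cl <- pop$cl_f * age_multiplier(pop$theta_age_cl, cov$age, pop$m_age) *
    pop$theta_sex_cl^cov$sex * exp(eta_of(re, "cl"))
  clm <- pop$clm_f * age_multiplier(pop$theta_age_clm, cov$age, pop$m_age) *
    exp(eta_of(re, "clm"))
  ind <- list(model = "dabohd",
              cl = cl,
              v2 = pop$v2_f * exp(eta_of(re, "v2")),
              ka = pop$ka,
              q = pop$q_f,
              v4 = pop$v4_f,
              clm = clm,
              v3 = pop$v3_f * exp(eta_of(re, "v3")),
              qm = pop$qm_f,
              v5 = pop$v5_f,
              tlag = pop$tlag,
              mw_dab = pop$mw_dab, mw_ohd = pop$mw_ohd)
  if (!is.null(re) && length(re$kappa))
    ind$cl_by_occ <- cl * exp(re$kappa)
  stopifnot(all(unlist(ind[c("cl", "v2", "clm", "v3")]) > 0))
  class(ind) <- "individual_params"
  ind
}

#' @export
apply_covariates.pop_tra <- function(pop, cov = NULL, re = NULL) {
  ind <- list(model = "tra",
              cl = pop$cl_f * exp(eta_of(re, "cl")),
              v2 = pop$v2_f,
              ka = pop$ka,
              q = pop$q_f * exp(eta_of(re, "q")),
              v3 = pop$v3_f,
              tlag = pop$tlag)
  class(ind) <- "individual_params"
  ind
}

#' IIV parameter names of a population model
#' @param pop A population parameter set.
#' @return Character vector of eta names.
#' @keywords internal
iiv_names <- function(pop) {
  if (inherits(pop, "pop_dabohd")) c("cl", "v2", "clm", "v3") else c("cl", "q")
}

iiv_cvs <- function(pop) {
  if (inherits(pop, "pop_dabohd"))
    c(cl = pop$iiv_cl, v2 = pop$iiv_v2, clm = pop$iiv_clm, v3 = pop$iiv_v3)
  else c(cl = pop$iiv_cl, q = pop$iiv_q)
}

#' Convert a lognormal coefficient of variation to a log-scale variance
#'
#' Uses the exact lognormal relation `omega^2 = log(1 + CV^2)`.
#' @param cv Coefficient of variation as a fraction.
#' @return Log-scale variance.
#' @export
cv_to_omega2 <- function(cv) log(1 + cv^2)
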
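# Exposure-toxicity and exposure-survival statistics with the study's
# variable codings.

#' Dichotomized baseline and exposure covariates
#'
#' All cut-offs are inclusive on the right (">="): ECOG PS >= 2,
#' number of metastatic sites >= 3, LDH >= 1.5 x the upper normal limit,
#' metabolic ratio >= 1.
#'
#' @param data Data frame with any of `ecog_ps`, `n_met_sites`, `ldh_ratio`,
#'   `auc_m3_ratio` columns.
#' @return `data` with added 0/1 columns `ecog_ge2`, `sites_ge3`,
#'   `ldh_ge15`, `ratio_ge_1` (when the source columns exist).
#' @export
code_covariates <- function(data) {
  if ("ecog_ps" %in% names(data))
    data$ecog_ge2 <- as.integer(data$ecog_ps >= 2)
  if ("n_met_sites" %in% names(data))
    data$sites_ge3 <- as.integer(data$n_met_sites >= 3)
  if ("ldh_ratio" %in% names(data))
    data$ldh_ge15 <- as.integer(data$ldh_ratio >= 1.5)
  if ("auc_m3_ratio" %in% names(data))
    data$ratio_ge_1 <- as.integer(data$auc_m3_ratio >= 1)
  data
}

# Per-subject exposure under the DLT comparison rule: patients with a DLT
# contribute the last occasion AUC before onset; patients without a DLT
# contribute their mean over all occasions.
dlt_exposure_values <- function(exposures, outcomes, dlt_col, day_col,
                                variable) {
  out <- data.frame(id = outcomes$id, dlt = outcomes[[dlt_col]],
                    value = NA_real_)
  for (i in seq_len(nrow(out))) {
    e <- exposures[exposures$id == out$id[i], , drop = FALSE]
    if (!nrow(e)) next
    if (out$dlt[i] == 1) {
      pre <- e[e$day <= outcomes[[day_col]][i], , drop = FALSE]
      if (!nrow(pre)) next  # no assessment before onset: excluded
      out$value[i] <- pre[[variable]][which.max(pre$day)]
    } else {
      out$value[i] <- mean(e[[variable]])
    }
  }
  out[!is.na(out$value), , drop = FALSE]
}

#' Exposure (or baseline) contrast between DLT and non-DLT patients
#'
#' For exposure variables, the DLT group is summarized by the last AUC
#' before toxicity onset and the non-DLT group by the average AUC over the
#' treatment course; baseline variables are compared as-is.  Continuous
#' variables use the two-sided Wilcoxon rank-sum test (exact when both
#' groups have < 20 subjects and no ties, mid-ranks with the normal
#' approximation otherwise); binary variables use Fisher's exact test.
#'
#' @param exposures Per-occasion exposure table (`id`, `occ`, `day`, AUC
#'   columns), as from [exposure_summary()].
#' @param outcomes Per-subject outcome table with `id`, `dlt_dab`/`dlt_tra`
#'   flags, onset days `dlt_dab_day`/`dlt_tra_day`, and baseline columns.
#' @param drug `"DAB"` or `"TRA"` (selects the DLT endpoint).
#' @param variable Column to contrast: an exposure column of `exposures`
#'   (e.g. `"auc_dab"`) or a baseline column of `outcomes`.
#' @return A list with `summary` (per-group n, median, min, max or counts),
#'   `p`, `test`, `variable`.
#' @export
dlt_exposure_contrast <- function(exposures, outcomes,
                                  drug = c("DAB", "TRA"),
                                  variable = "auc_dab") {
  drug <- match.arg(drug)
  dlt_col <- if (drug == "DAB") "dlt_dab" else "dlt_tra"
  day_col <- paste0(dlt_col, "_day")
  if (variable %in% names(exposures)) {
    vals <- dlt_exposure_values(exposures, outcomes, dlt_col, day_col,
                                variable)
  } else if (variable %in% names(outcomes)) {
    vals <- data.frame(id = outcomes$id, dlt = outcomes[[dlt_col]],
                       value = outcomes[[variable]])
    vals <- vals[!is.na(vals$value), , drop = FALSE]
  } else stop("variable '", variable, "' found in neither table")
  g1 <- vals$value[vals$dlt == 1]
  g0 <- vals$value[vals$dlt == 0]
  if (!length(g1)) stop("DLT group is empty")
  if (!length(g0)) stop("non-DLT group is empty")
  binary <- all(vals$value %in% c(0, 1))
  if (binary) {
    tab <- table(factor(vals$dlt, c(1, 0)), factor(vals$value, c(0, 1)))
    p <- stats::fisher.test(tab)$p.value
    smry <- data.frame(group = c("DLT", "no DLT"), n = c(length(g1), length(g0)),
                       n_positive = c(sum(g1), sum(g0)))
    test <- "Fisher exact"
  } else {
    exact <- length(g1) < 20 && length(g0) < 20 &&
      !any(duplicated(vals$value))
    p <- suppressWarnings(
      stats::wilcox.test(g1, g0, exact = exact, correct = !exact)$p.value)
    smry <- data.frame(group = c("DLT", "no DLT"),
                       n = c(length(g1), length(g0)),
                       median = c(stats::median(g1), stats::median(g0)),
                       min = c(min(g1), min(g0)), max = c(max(g1), max(g0)))
    test <- if (exact) "Wilcoxon rank-sum (exact)"
            else "Wilcoxon rank-sum (normal approximation)"
  }
  list(summary = smry, p = p, test = test, variable = variable)
}

# Exposure scaling for hazard ratios: DAB/OHD/composite AUC_M3 per
# 1000 ng*h/mL, TRA per 100 ng*h/mL.
SURV_VARS <- list(
  sex = 1, age = 1, bmi = 1, ecog_ge2 = 1, sites_ge3 = 1,
  cerebral_mets = 1, ppi = 1, ldh_ge15 = 1,
  auc_m3_dab = 1000, auc_m3_ohd = 1000, auc_m3_composite = 1000,
  ratio_ge_1 = 1, auc_m3_tra = 100)

#' Univariate and stepwise multivariate Cox survival analysis
#'
#' Fits univariate proportional-hazards models for the study's variable
#' list with its codings (ECOG PS >= 2, >= 3 metastatic sites, LDH >= 1.5N,
#' metabolic ratio >= 1 as the 4th-quartile cut-off; AUC_M3 exposures scaled
#' per 1000 ng*h/mL for DAB/OHD/composite and per 100 ng*h/mL for TRA — the
#' scaling is recorded in the output), then a backward-stepwise multivariate
#' model starting from every variable significant at the 5% level in the
#' univariate step and eliminating at p >= 0.05.
#'
#' @param data Per-subject data frame with survival columns
#'   `<endpoint>_months`, `<endpoint>_event` and the covariate columns (any
#'   subset of `names(SURV_VARS)`; dichotomizations can be prepared with
#'   [code_covariates()]).
#' @param endpoint `"os"` or `"pfs"`.
#' @param alpha Significance level for entry and elimination.
#' @param min_events Guard: the multivariate step needs at least this many
#'   events.
#' @return A list with `univariate` (variable, scale, HR, CI, p, flag),
#'   `multivariate` (or NULL), `n`, `n_events`.
#' @export
survival_analysis <- function(data, endpoint = c("os", "pfs"), alpha = 0.05,
                              min_events = 10) {
  endpoint <- match.arg(endpoint)
  tcol <- paste0(endpoint, "_months"); ecol <- paste0(endpoint, "_event")
  stopifnot(all(c(tcol, ecol) %in% names(data)))
  if (any(data[[tcol]] < 0)) stop("negative survival times")
  n_events <- sum(data[[ecol]])
  if (n_events == 0) stop("no events observed for endpoint ", endpoint)
  y <- survival::Surv(data[[tcol]], data[[ecol]])
  vars <- intersect(names(SURV_VARS), names(data))
  fit_one <- function(df, vv) {
    flag <- ""
    fml <- stats::as.formula(paste("y ~", paste(vv, collapse = " + ")))
    fit <- withCallingHandlers(
      tryCatch(survival::coxph(fml, data = df), error = function(e) {
        flag <<- paste("error:", conditionMessage(e)); NULL
      }),
      warning = function(w) {
        flag <<- paste("warning:", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    list(fit = fit, flag = flag)
  }
  scaled <- data
  for (v in vars) scaled[[v]] <- data[[v]] / SURV_VARS[[v]]
  uni <- list()
  for (v in vars) {
    if (all(is.na(scaled[[v]])) || length(unique(stats::na.omit(scaled[[v]]))) < 2)
      next
    r <- fit_one(scaled, v)
    if (is.null(r$fit)) {
      uni[[v]] <- data.frame(variable = v, scale = SURV_VARS[[v]],
                             hr = NA, lo = NA, hi = NA, p = NA, flag = r$flag)
      next
    }
    s <- summary(r$fit)
    uni[[v]] <- data.frame(variable = v, scale = SURV_VARS[[v]],
                           hr = s$conf.int[1, "exp(coef)"],
                           lo = s$conf.int[1, "lower .95"],
                           hi = s$conf.int[1, "upper .95"],
                           p = s$coefficients[1, "Pr(>|z|)"],
                           flag = r$flag)
  }
  uni <- do.call(rbind, uni)
  rownames(uni) <- NULL
  multi <- NULL
  cand <- uni$variable[!is.na(uni$p) & uni$p < alpha]
  if (length(cand) && n_events >= min_events) {
    current <- cand
    repeat {
      r <- fit_one(scaled, current)
      if (is.null(r$fit)) break
      s <- summary(r$fit)
      ps <- s$coefficients[, "Pr(>|z|)"]
      if (max(ps) < alpha || length(current) == 1) {
        multi <- data.frame(variable = current,
                            scale = unlist(SURV_VARS[current]),
                            hr = s$conf.int[, "exp(coef)"],
                            lo = s$conf.int[, "lower .95"],
                            hi = s$conf.int[, "upper .95"],
                            p = ps, flag = r$flag)
        rownames(multi) <- NULL
        break
      }
      current <- current[-which.max(ps)]
    }
  }
  list(univariate = uni, multivariate = multi,
       n = nrow(data), n_events = n_events)
}
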
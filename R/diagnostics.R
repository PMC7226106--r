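# Model diagnostics: prediction-corrected visual predictive check and
# nonparametric (subject-resampling) bootstrap.

# Typical-subject predictions (eta = 0) for observation design rows, with
# caching over identical (covariates, dose, interval, tad) combinations.
typical_pred <- function(design, pop, cov_tab) {
  pred <- numeric(nrow(design))
  if (inherits(pop, "pop_dabohd")) {
    key <- paste(cov_tab$age[match(design$ID, cov_tab$id)],
                 cov_tab$sex[match(design$ID, cov_tab$id)],
                 design$dose, design$interval, signif(design$tad, 10))
  } else {
    key <- paste(design$dose, design$interval, signif(design$tad, 10))
  }
  for (k in unique(key)) {
    idx <- which(key == k)
    i1 <- idx[1]
    cov <- if (inherits(pop, "pop_dabohd"))
      covariates(age = cov_tab$age[match(design$ID[i1], cov_tab$id)],
                 sex = cov_tab$sex[match(design$ID[i1], cov_tab$id)])
    else NULL
    ind <- apply_covariates(pop, cov)
    P <- ss_conc_mat(ind, design$dose[i1], design$interval[i1],
                     design$tad[i1])
    pred[idx] <- if (ind$model == "dabohd") {
      ifelse(design$ANALYTE[idx] == "DAB", P[1, "dab"], P[1, "ohd"])
    } else P[1, "tra"]
  }
  pred
}

#' Prediction-corrected visual predictive check
#'
#' Observations are normalized by the typical-subject (eta = 0) population
#' prediction at their own design, `pcY = Y * median(PRED_bin) / PRED`, and
#' compared with `n_sim` datasets simulated from the model under the same
#' designs and the same correction.  Time bins are quantile-based on time
#' after dose.  Observations whose population prediction is at the
#' numerical floor are excluded and counted.
#'
#' @param events Event table with observation and dose rows (and AGE/SEX
#'   columns for the DAB/OHD model).
#' @param pop Population parameter set.
#' @param n_sim Number of simulated replicates (>= 100).
#' @param bins Number of quantile bins on time after dose.
#' @param seed RNG seed for the simulations.
#' @param iiv,iov,ruv Variability switches for the simulated replicates.
#' @param ci Width of the simulated confidence band around each percentile.
#' @param probs Percentiles summarized per bin.
#' @return A `pcvpc` object: data frame with one row per analyte x bin
#'   (bin edges, n, observed percentiles `obs_p*`, simulated band
#'   `sim_p*_lo` / `sim_p*_hi`), with attributes `n_excluded`, `n_sim`,
#'   `seed`.
#' @export
pcvpc <- function(events, pop, n_sim = 500, bins = 8, seed = 1,
                  iiv = TRUE, iov = TRUE, ruv = TRUE, ci = 0.90,
                  probs = c(0.05, 0.50, 0.95)) {
  if (n_sim < 100) stop("n_sim must be >= 100")
  if ("BLQ" %in% names(events)) events <- blq_filter(events)
  design <- obs_design(events)
  analytes <- if (inherits(pop, "pop_dabohd")) c("DAB", "OHD") else "TRA"
  design <- design[design$ANALYTE %in% analytes, , drop = FALSE]
  if (!nrow(design)) stop("no observations to diagnose")
  cov_cols <- intersect(c("AGE", "SEX"), names(events))
  cov_tab <- unique(events[, c("ID", cov_cols), drop = FALSE])
  names(cov_tab) <- c("id", tolower(cov_cols))
  pred <- typical_pred(design, pop, cov_tab)
  keep <- pred > 1e-6
  n_excluded <- sum(!keep)
  design <- design[keep, , drop = FALSE]
  pred <- pred[keep]

  edges <- unique(stats::quantile(design$tad, probs = seq(0, 1, length.out =
                                                            bins + 1)))
  design$bin <- cut(design$tad, breaks = edges, include.lowest = TRUE)
  bin_key <- paste(design$ANALYTE, design$bin)
  med_pred <- tapply(pred, bin_key, stats::median)
  pc_obs <- design$DV * med_pred[bin_key] / pred

  # simulate replicates under the same designs
  ids <- unique(design$ID)
  n <- length(ids)
  n_occ_max <- max(tapply(design$OCC, design$ID,
                          function(x) length(unique(x))))
  subj_cov <- lapply(ids, function(id) {
    if (!inherits(pop, "pop_dabohd")) return(NULL)
    i <- match(id, cov_tab$id)
    covariates(age = cov_tab$age[i], sex = cov_tab$sex[i])
  })
  # per-subject prediction groups (occasion x dose x interval), fixed across
  # replicates: row indices, design constants, analyte selector
  subj_groups <- lapply(ids, function(id) {
    rows <- which(design$ID == id)
    d_i <- design[rows, , drop = FALSE]
    grp <- if (iov) paste(d_i$OCC, d_i$dose, d_i$interval)
           else paste(d_i$dose, d_i$interval)
    lapply(split(seq_along(rows), grp), function(k) list(
      rows = rows[k], occ_index = match(d_i$OCC[k[1]],
                                        sort(unique(d_i$OCC))),
      dose = d_i$dose[k[1]], interval = d_i$interval[k[1]],
      tad = d_i$tad[k], is_dab = d_i$ANALYTE[k] == "DAB"))
  })
  pc_quant <- function(v) {
    out <- matrix(NA_real_, length(probs), length(med_pred),
                  dimnames = list(NULL, names(med_pred)))
    for (k in names(med_pred)) {
      idx <- which(bin_key == k)
      out[, k] <- stats::quantile(v[idx], probs)
    }
    out
  }
  sim_q <- array(NA_real_, c(n_sim, length(probs), length(med_pred)))
  with_seed(seed, for (r in seq_len(n_sim)) {
    dr <- draw_random_effects(pop, n, n_occ = if (iov) n_occ_max else 0,
                              iiv = iiv, iov = iov)
    ysim <- numeric(nrow(design))
    for (i in seq_len(n)) {
      ind <- apply_covariates(pop, subj_cov[[i]], re_for_subject(dr, i))
      for (g in subj_groups[[i]]) {
        ind_k <- ind
        if (!is.null(ind$cl_by_occ) && g$occ_index <= length(ind$cl_by_occ))
          ind_k$cl <- unname(ind$cl_by_occ[g$occ_index])
        P <- ss_conc_mat(ind_k, g$dose, g$interval, g$tad)
        ysim[g$rows] <- if (ind$model == "dabohd")
          ifelse(g$is_dab, P[, "dab"], P[, "ohd"])
        else P[, "tra"]
      }
    }
    if (ruv) {
      if (inherits(pop, "pop_dabohd")) {
        e <- apply_residual_error(ysim, ysim, pop)
        is_dab <- design$ANALYTE == "DAB"
        ysim[is_dab] <- e$dab[is_dab]
        ysim[!is_dab] <- e$ohd[!is_dab]
      } else ysim <- apply_residual_error_tra(ysim, pop)
    }
    sim_q[r, , ] <- pc_quant(ysim * med_pred[bin_key] / pred)
  })
  a <- (1 - ci) / 2
  obs_q <- pc_quant(pc_obs)
  rows <- list()
  for (k in seq_along(med_pred)) {
    key <- names(med_pred)[k]
    an <- sub(" .*", "", key)
    lab <- sub("^[A-Z]+ ", "", key)
    row <- data.frame(analyte = an, bin = lab,
                      n = sum(bin_key == key))
    for (p in seq_along(probs)) {
      pn <- sprintf("p%02d", round(100 * probs[p]))
      row[[paste0("obs_", pn)]] <- obs_q[p, k]
      row[[paste0("sim_", pn, "_lo")]] <- stats::quantile(sim_q[, p, k], a)
      row[[paste0("sim_", pn, "_hi")]] <- stats::quantile(sim_q[, p, k], 1 - a)
    }
    rows[[k]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("pcvpc", "data.frame"),
            n_excluded = n_excluded, n_sim = n_sim, seed = seed)
}

#' Nonparametric bootstrap of a population fit
#'
#' Resamples subjects with replacement, refits each replicate with the
#' supplied fitter, and summarizes per-parameter medians and percentile
#' intervals.  Failed replicates are caught, counted and excluded.
#'
#' @param events Event table (>= 2 subjects).
#' @param n_rep Number of replicates.
#' @param fitter Function taking a resampled event table and returning a
#'   named numeric vector of estimates; defaults to the naive-pooled
#'   DAB/OHD fit.
#' @param seed RNG seed (fixes the replicate index sets).
#' @param indices Optional list of subject-index vectors overriding the
#'   random resampling (e.g. the identity permutation).
#' @param probs Interval percentiles.
#' @return A list with `median`, `ci`, `estimates` (replicate x parameter
#'   matrix), `n_failed`, `indices`.
#' @export
bootstrap_fit <- function(events, n_rep = 200,
                          fitter = function(ev)
                            fit_naive_pooled(ev, "dabohd")$estimates,
                          seed = 1, indices = NULL,
                          probs = c(0.025, 0.975)) {
  ids <- unique(events$ID)
  if (length(ids) < 2) stop("bootstrap needs at least 2 subjects")
  if (is.null(indices))
    indices <- with_seed(seed, lapply(seq_len(n_rep), function(r)
      sample.int(length(ids), replace = TRUE)))
  res <- vector("list", length(indices))
  for (r in seq_along(indices)) {
    idx <- indices[[r]]
    ev_r <- do.call(rbind, lapply(seq_along(idx), function(j) {
      e <- events[events$ID == ids[idx[j]], , drop = FALSE]
      e$ID <- paste0("B", j)
      e
    }))
    res[r] <- list(tryCatch(fitter(ev_r), error = function(e) NULL))
  }
  ok <- !vapply(res, is.null, logical(1))
  if (!any(ok)) stop("all bootstrap replicates failed")
  est <- do.call(rbind, res[ok])
  list(median = apply(est, 2, stats::median),
       ci = apply(est, 2, stats::quantile, probs = probs),
       estimates = est, n_failed = sum(!ok), indices = indices)
}
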
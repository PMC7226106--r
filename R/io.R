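# Event-table I/O: a NONMEM-style CSV interchange format with schema
# validation and quantification-limit handling.
#
# Columns: ID; TIME (h since first dose); EVID (1 dose row / 0 observation);
# AMT (mg, dose rows only); II (dosing interval h, dose rows; dosing repeats
# every II hours from the row's TIME until the drug's next dose row); DV
# (ng/mL, observation rows); ANALYTE (DAB, OHD or TRA; dose rows use DAB for
# the dabrafenib regimen); OCC (sampling-occasion id, observation rows);
# optional covariate columns (AGE, SEX, ...) repeated on every row.

EVENT_COLS <- c("ID", "TIME", "EVID", "AMT", "II", "DV", "ANALYTE", "OCC")

#' Default lower limits of quantification (ng/mL)
#'
#' Assay calibration ranges: 10-2000 ng/mL for DAB and OHD, 5-50 ng/mL for
#' TRA; observations below the lower limit are flagged on read and excluded
#' from fitting.
#' @keywords internal
DEFAULT_LLOQ <- c(DAB = 10, OHD = 10, TRA = 5)

#' Validate an event table
#'
#' Checks the schema contract: required columns present; EVID in {0, 1};
#' TIME non-decreasing within subject; dose amounts positive; every subject
#' has a dose row at or before its first observation; analytes known.
#' Violations are collected and reported with row numbers.
#'
#' @param events Event table data frame.
#' @return Invisibly `events`; stops with the full list of violations
#'   otherwise.
#' @export
validate_event_table <- function(events) {
  errs <- character(0)
  missing_cols <- setdiff(EVENT_COLS, names(events))
  if (length(missing_cols))
    stop("event table lacks columns: ", paste(missing_cols, collapse = ", "))
  bad <- which(!events$EVID %in% c(0L, 1L))
  if (length(bad)) errs <- c(errs, paste0("row ", bad, ": EVID must be 0 or 1"))
  bad <- which(!events$ANALYTE %in% c("DAB", "OHD", "TRA"))
  if (length(bad)) errs <- c(errs, paste0("row ", bad, ": unknown ANALYTE '",
                                          events$ANALYTE[bad], "'"))
  bad <- which(events$EVID == 1L & (is.na(events$AMT) | events$AMT <= 0))
  if (length(bad)) errs <- c(errs, paste0("row ", bad,
                                          ": dose row needs AMT > 0"))
  for (id in unique(events$ID)) {
    rows <- which(events$ID == id)
    tt <- events$TIME[rows]
    if (is.unsorted(tt))
      errs <- c(errs, paste0("row ", rows[which(diff(tt) < 0) + 1L],
                             ": TIME decreases within ID ", id))
    obs <- rows[events$EVID[rows] == 0L]
    dose <- rows[events$EVID[rows] == 1L]
    if (length(obs) && (!length(dose) ||
                        min(events$TIME[dose]) > min(events$TIME[obs])))
      errs <- c(errs, paste0("row ", obs[1],
                             ": observation before any dose for ID ", id))
  }
  if (length(errs))
    stop("event table schema violations:\n  ",
         paste(errs, collapse = "\n  "))
  invisible(events)
}

#' Write an event table to CSV
#' @param events Event table data frame (validated before writing).
#' @param path Output file.
#' @export
write_event_table <- function(events, path) {
  validate_event_table(events)
  utils::write.csv(events, path, row.names = FALSE, na = "")
}

#' Read and validate an event table from CSV
#'
#' Observations below the analyte's lower limit of quantification are
#' flagged in a logical `BLQ` column (they are excluded from fitting by
#' [blq_filter()]), and observation rows with missing time are flagged in
#' `MISSING_TIME`.  Counts of both are attached as the `exclusion_report`
#' attribute.
#'
#' @param path CSV file written by [write_event_table()].
#' @param lloq Named vector of lower limits of quantification (ng/mL).
#' @return The validated event table with `BLQ` and `MISSING_TIME` columns.
#' @export
read_event_table <- function(path, lloq = DEFAULT_LLOQ) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_event_table(ev)
  is_obs <- ev$EVID == 0L
  ev$BLQ <- is_obs & !is.na(ev$DV) & ev$DV < lloq[ev$ANALYTE]
  ev$MISSING_TIME <- is_obs & is.na(ev$TIME)
  attr(ev, "exclusion_report") <-
    c(n_blq = sum(ev$BLQ, na.rm = TRUE),
      n_missing_time = sum(ev$MISSING_TIME, na.rm = TRUE))
  ev
}

#' Drop flagged observations before fitting
#'
#' Removes observation rows flagged below the limit of quantification or
#' with missing time, reporting the counts (mirrors the analysis-dataset
#' exclusion rule).
#'
#' @param events Event table with `BLQ`/`MISSING_TIME` columns (as from
#'   [read_event_table()]); tables lacking the flags are returned unchanged.
#' @return The filtered table; counts dropped in attribute `dropped`.
#' @export
blq_filter <- function(events) {
  if (!"BLQ" %in% names(events)) return(events)
  drop <- (events$BLQ %in% TRUE) | (events$MISSING_TIME %in% TRUE)
  out <- events[!drop, , drop = FALSE]
  attr(out, "dropped") <- sum(drop)
  out
}

# Per-observation fitting design extracted from an event table: for each
# observation row, the drug's current dose amount, interval, and time after
# the (scheduled) previous dose.  Dose rows repeat every II hours from their
# TIME until the next dose row of the same drug.
obs_design <- function(events) {
  ev <- events
  obs <- ev[ev$EVID == 0L, , drop = FALSE]
  out <- obs[, intersect(c("ID", "TIME", "DV", "ANALYTE", "OCC"),
                         names(obs)), drop = FALSE]
  out$dose <- NA_real_; out$interval <- NA_real_; out$tad <- NA_real_
  for (r in seq_len(nrow(obs))) {
    drug <- if (obs$ANALYTE[r] %in% c("DAB", "OHD")) "DAB" else "TRA"
    dr <- ev[ev$EVID == 1L & ev$ID == obs$ID[r] & ev$ANALYTE == drug &
               ev$TIME <= obs$TIME[r], , drop = FALSE]
    if (!nrow(dr)) next
    k <- which.max(dr$TIME)
    out$dose[r] <- dr$AMT[k]
    out$interval[r] <- dr$II[k]
    out$tad[r] <- (obs$TIME[r] - dr$TIME[k]) %% dr$II[k]
  }
  out
}
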
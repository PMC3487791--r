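# Cohort data model: typed CSV I/O with row-level validation, scan-to-timepoint
# assignment, target-lesion selection and per-timepoint patient summaries.

#' Nominal follow-up schedule (months from first imatinib dose)
#'
#' Baseline is coded as 0; follow-up CTs are assigned to the nominal 3-, 6- and
#' 12-month timepoints.
#' @export
COHORT_TIMEPOINTS <- c(0L, 3L, 6L, 12L)

#' Measurement methods recognised by the cohort schema
#' @export
MEASUREMENT_METHODS <- c("manual", "semiauto")

#' Ordered size-change classes used by the 1D-vs-3D comparison
#' @export
CHANGE_LEVELS <- c("DECREASE", "NO_CHANGE", "INCREASE")

#' Ordered response categories (partial response, stable, progression)
#' @export
RESPONSE_LEVELS <- c("PR", "SD", "PD")

# volume unit convention: files carry mL, geometry works in mm^3
MM3_PER_ML <- 1000

.measurement_required <- c("patient_id", "lesion_id", "timepoint_months",
                           "method", "reader_id", "longest_diameter_mm",
                           "volume_mL")
.measurement_optional <- c("mean_density_HU", "r1_mm", "r2_mm", "r3_mm",
                           "new_lesion", "new_nodule")
.scan_required     <- c("patient_id", "scan_date", "months_from_first_imatinib")
.survival_required <- c("patient_id", "os_months_from_first_imatinib", "event")

.cohort_schemas <- list(
  measurements = list(required = .measurement_required,
                      optional = .measurement_optional),
  scans        = list(required = .scan_required, optional = character()),
  survival     = list(required = .survival_required, optional = character())
)

.validate_measurement_rows <- function(df) {
  reason <- rep(NA_character_, nrow(df))
  flag <- function(bad, msg) {
    bad[is.na(bad)] <- TRUE
    reason[is.na(reason) & bad] <<- msg
  }
  flag(!is.finite(df$longest_diameter_mm) | df$longest_diameter_mm <= 0,
       "non-positive diameter")
  flag(!is.finite(df$volume_mL) | df$volume_mL <= 0, "non-positive volume")
  flag(!(df$timepoint_months %in% COHORT_TIMEPOINTS),
       "timepoint not in 0/3/6/12 months")
  flag(!(df$method %in% MEASUREMENT_METHODS), "unknown method")

  has_axis <- cbind(!is.na(df$r1_mm), !is.na(df$r2_mm), !is.na(df$r3_mm))
  n_axes <- rowSums(has_axis)
  flag(n_axes > 0 & n_axes < 3, "incomplete semi-axes")
  full <- which(n_axes == 3 & is.na(reason))
  if (length(full)) {
    r1 <- df$r1_mm[full]; r2 <- df$r2_mm[full]; r3 <- df$r3_mm[full]
    bad_pos <- r1 <= 0 | r2 <= 0 | r3 <= 0
    reason[full[bad_pos]] <- "non-positive semi-axis"
    bad_ord <- !bad_pos & (r1 > r2 | r2 > r3)
    reason[full[bad_ord]] <- "semi-axes not in ascending order"
    v_axes <- ellipsoid_volume(r1, r2, r3) / MM3_PER_ML
    bad_vol <- !bad_pos & !bad_ord &
      abs(v_axes - df$volume_mL[full]) > 1e-3 * df$volume_mL[full]
    reason[full[bad_vol]] <- "semi-axes inconsistent with volume (>0.1%)"
  }
  reason
}

.validate_scan_rows <- function(df) {
  reason <- rep(NA_character_, nrow(df))
  bad <- !is.finite(df$months_from_first_imatinib) |
    df$months_from_first_imatinib < 0
  bad[is.na(bad)] <- TRUE
  reason[bad] <- "negative or missing months_from_first_imatinib"
  reason
}

.validate_survival_rows <- function(df) {
  reason <- rep(NA_character_, nrow(df))
  bad_t <- !is.finite(df$os_months_from_first_imatinib) |
    df$os_months_from_first_imatinib < 0
  bad_t[is.na(bad_t)] <- TRUE
  reason[bad_t] <- "negative or missing OS time"
  bad_e <- is.na(reason) & !(df$event %in% c(0, 1))
  reason[bad_e] <- "event flag not 0/1"
  reason
}

.coerce_measurements <- function(df) {
  df$patient_id <- as.character(df$patient_id)
  df$lesion_id  <- as.character(df$lesion_id)
  df$reader_id  <- as.character(df$reader_id)
  df$method     <- as.character(df$method)
  df$timepoint_months <- as.integer(df$timepoint_months)
  for (col in setdiff(.measurement_optional, names(df))) df[[col]] <- NA_real_
  df$new_lesion <- !is.na(df$new_lesion) & df$new_lesion != 0
  df$new_nodule <- !is.na(df$new_nodule) & df$new_nodule != 0
  df
}

#' Read a cohort CSV file into validated typed records
#'
#' Parses one of the three cohort schemas and validates every row against the
#' domain invariants (positive sizes, known methods/timepoints, semi-axes
#' consistent with the recorded volume to 0.1% when present). Rows failing an
#' invariant are rejected with a row-indexed diagnostic rather than aborting
#' the parse.
#'
#' @param path path to a UTF-8, comma-separated file with a header.
#' @param schema one of `"measurements"`, `"scans"`, `"survival"`.
#' @return A list of class `cohort_io` with elements `records` (data frame of
#'   accepted rows), `rejected` (data frame with `row` and `reason`) and
#'   `report` (list with `n_accepted`, `n_rejected`).
#' @export
read_cohort <- function(path, schema = c("measurements", "scans", "survival")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  spec <- .cohort_schemas[[schema]]
  missing_cols <- setdiff(spec$required, names(df))
  if (length(missing_cols))
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- switch(schema,
    measurements = .coerce_measurements(df),
    scans = {
      df$patient_id <- as.character(df$patient_id)
      df$scan_date <- as.Date(df$scan_date)
      df
    },
    survival = {
      df$patient_id <- as.character(df$patient_id)
      df
    })
  reason <- switch(schema,
    measurements = .validate_measurement_rows(df),
    scans = .validate_scan_rows(df),
    survival = .validate_survival_rows(df))
  ok <- is.na(reason)
  rejected <- data.frame(row = which(!ok), reason = reason[!ok],
                         stringsAsFactors = FALSE)
  out <- list(records = df[ok, , drop = FALSE],
              rejected = rejected,
              report = list(schema = schema,
                            n_accepted = sum(ok),
                            n_rejected = sum(!ok)))
  rownames(out$records) <- NULL
  class(out) <- "cohort_io"
  out
}

#' @export
print.cohort_io <- function(x, ...) {
  cat(sprintf("<cohort_io: %s> %d accepted, %d rejected\n",
              x$report$schema, x$report$n_accepted, x$report$n_rejected))
  if (nrow(x$rejected)) {
    cat("rejected rows:\n")
    print(utils::head(x$rejected, 10))
  }
  invisible(x)
}

#' Write cohort records to CSV
#'
#' Inverse of [read_cohort()]: valid records written by `write_cohort` and
#' re-read compare record-for-record equal (empty cells encode missing values).
#'
#' @param records data frame of cohort records.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path) {
  df <- records
  for (col in c("new_lesion", "new_nodule"))
    if (col %in% names(df)) df[[col]] <- as.integer(df[[col]])
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Assign the closest scan to a nominal follow-up timepoint
#'
#' Picks, among one patient's scans, the one closest in time to the nominal
#' timepoint (ties broken toward the earlier scan). Scans farther than
#' `window_months` from the nominal timepoint are not eligible, so the result
#' may be absent (`NULL`). The default window of 1.5 months covers the spread
#' of actual scan dates typically seen around scheduled 3/6/12-month CTs.
#'
#' @param scans data frame of scan records for one patient (may be empty).
#' @param nominal nominal timepoint in months: 3, 6 or 12.
#' @param window_months half-width of the eligibility window.
#' @return a single-row data frame (the chosen scan) or `NULL`.
#' @export
assign_timepoint <- function(scans, nominal, window_months = 1.5) {
  if (!nominal %in% c(3, 6, 12))
    stop("nominal timepoint must be 3, 6 or 12 months")
  if (is.null(scans) || nrow(scans) == 0) return(NULL)
  m <- scans$months_from_first_imatinib
  dist <- abs(m - nominal)
  eligible <- which(dist <= window_months + 1e-9)
  if (!length(eligible)) return(NULL)
  pick <- eligible[order(dist[eligible], m[eligible])][1]
  scans[pick, , drop = FALSE]
}

#' Select up to two target lesions at baseline
#'
#' Target lesions are the one or two lesions with the largest baseline longest
#' diameter (RECIST 1.1 allows at most two target lesions per organ). Ties are
#' broken by lexicographic lesion id, making the selection deterministic and
#' independent of input row order. If several rows (readers) measure the same
#' lesion, their mean diameter is used for ranking.
#'
#' @param baseline measurement rows for one patient at baseline (0 months).
#' @return list with `patient_id` and `lesion_ids` (length 1 or 2).
#' @export
select_target_lesions <- function(baseline) {
  if (is.null(baseline) || nrow(baseline) == 0) stop("no baseline lesions")
  if (length(unique(baseline$patient_id)) != 1)
    stop("baseline rows must belong to a single patient")
  if (any(baseline$timepoint_months != 0))
    stop("baseline rows must be at 0 months")
  d <- tapply(baseline$longest_diameter_mm, baseline$lesion_id, mean)
  ids <- names(d)
  ord <- order(-unname(d), ids)
  list(patient_id = baseline$patient_id[1],
       lesion_ids = ids[ord][seq_len(min(2L, length(ids)))])
}

#' Summarise target-lesion measurements at one timepoint
#'
#' Computes the RECIST sum of longest diameters, the total volume, the mean
#' density, and (when baseline per-lesion rows are supplied) the mean of the
#' per-lesion relative density changes `100 * (HU_t - HU_0) / HU_0`. All target
#' lesions must be measured at the timepoint by a single method, one row per
#' lesion.
#'
#' @param measurements one patient's target-lesion rows at one timepoint.
#' @param baseline optional baseline rows for the same lesions (needed for the
#'   density-change summary).
#' @param target optional character vector of target lesion ids; if supplied,
#'   an error names any target lesion missing from `measurements`.
#' @return single-row data frame with columns `patient_id`,
#'   `timepoint_months`, `method`, `n_lesions`, `sum_longest_diameter_mm`,
#'   `total_volume_mL`, `mean_density_HU`, `mean_relative_density_change_pct`;
#'   the lesion ids are carried in attribute `lesion_ids`.
#' @export
summarize_timepoint <- function(measurements, baseline = NULL, target = NULL) {
  if (is.null(measurements) || nrow(measurements) == 0)
    stop("no measurements to summarise")
  if (length(unique(measurements$patient_id)) != 1)
    stop("measurements must belong to a single patient")
  if (length(unique(measurements$timepoint_months)) != 1)
    stop("measurements must share a timepoint")
  if (length(unique(measurements$method)) != 1)
    stop("measurements must share a method")
  if (anyDuplicated(measurements$lesion_id))
    stop("multiple rows per lesion: ",
         paste(unique(measurements$lesion_id[
           duplicated(measurements$lesion_id)]), collapse = ", "))
  if (!is.null(target)) {
    missing_ids <- setdiff(target, measurements$lesion_id)
    if (length(missing_ids))
      stop("target lesion(s) missing at timepoint: ",
           paste(missing_ids, collapse = ", "))
    measurements <- measurements[measurements$lesion_id %in% target, ,
                                 drop = FALSE]
  }
  dens <- measurements$mean_density_HU
  density_change <- NA_real_
  if (!is.null(baseline) && nrow(baseline)) {
    idx <- match(measurements$lesion_id, baseline$lesion_id)
    hu0 <- baseline$mean_density_HU[idx]
    both <- !is.na(dens) & !is.na(hu0) & hu0 != 0
    if (any(both))
      density_change <- mean(100 * (dens[both] - hu0[both]) / hu0[both])
  }
  out <- data.frame(
    patient_id = measurements$patient_id[1],
    timepoint_months = measurements$timepoint_months[1],
    method = measurements$method[1],
    n_lesions = nrow(measurements),
    sum_longest_diameter_mm = sum(measurements$longest_diameter_mm),
    total_volume_mL = sum(measurements$volume_mL),
    mean_density_HU = if (all(is.na(dens))) NA_real_ else mean(dens, na.rm = TRUE),
    mean_relative_density_change_pct = density_change,
    stringsAsFactors = FALSE)
  attr(out, "lesion_ids") <- sort(measurements$lesion_id)
  out
}
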
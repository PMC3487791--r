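# Response classifiers: RECIST 1.1 on summed diameters, volumetric criteria on
# total target-lesion volume (sphere-derived and ellipsoid cut-offs), Choi
# size/density criteria, and the raw >=20% change classifier.
#
# All cut-offs are boundary-inclusive toward the more extreme category and all
# changes are computed versus baseline (not nadir).

#' Relative change in percent
#'
#' @param baseline positive baseline value(s).
#' @param value follow-up value(s).
#' @return `100 * (value - baseline) / baseline`.
#' @export
relative_change <- function(baseline, value) {
  if (any(!is.finite(baseline)) || any(baseline <= 0))
    stop("baseline must be positive")
  100 * (value - baseline) / baseline
}

#' Volume of a sphere from its diameter
#'
#' @param diameter positive diameter(s).
#' @return `pi * diameter^3 / 6`, in the cube of the input unit.
#' @export
sphere_volume <- function(diameter) {
  if (any(!is.finite(diameter)) || any(diameter <= 0))
    stop("diameter must be positive")
  pi * diameter^3 / 6
}

#' Volume of an ellipsoid from its semi-axes
#'
#' @param r1,r2,r3 positive semi-axis lengths.
#' @return `(4/3) * pi * r1 * r2 * r3`.
#' @export
ellipsoid_volume <- function(r1, r2, r3) {
  if (any(!is.finite(c(r1, r2, r3))) || any(c(r1, r2, r3) <= 0))
    stop("semi-axes must be positive")
  (4 / 3) * pi * r1 * r2 * r3
}

#' Construct a PR/PD cut-off set
#'
#' @param criteria criteria label (e.g. `"RECIST"`, `"SPHERE"`, `"ELLIPSOID"`).
#' @param pr_cutoff_pct partial-response cut-off (non-positive percent change).
#' @param pd_cutoff_pct progression cut-off (non-negative percent change).
#' @return list of class `cutoff_set`.
#' @export
cutoff_set <- function(criteria, pr_cutoff_pct, pd_cutoff_pct) {
  stopifnot(is.numeric(pr_cutoff_pct), is.numeric(pd_cutoff_pct))
  if (pr_cutoff_pct > 0 || pd_cutoff_pct < 0)
    stop("require pr_cutoff_pct <= 0 <= pd_cutoff_pct")
  structure(list(criteria = criteria,
                 pr_cutoff_pct = pr_cutoff_pct,
                 pd_cutoff_pct = pd_cutoff_pct),
            class = "cutoff_set")
}

#' @export
print.cutoff_set <- function(x, ...) {
  cat(sprintf("<cutoff_set %s> PR <= %+.4g%%, PD >= %+.4g%%\n",
              x$criteria, x$pr_cutoff_pct, x$pd_cutoff_pct))
  invisible(x)
}

#' RECIST 1.1 cut-offs on the sum of longest diameters (-30% / +20%)
#' @return a [cutoff_set()].
#' @export
recist_cutoffs <- function() cutoff_set("RECIST", -30, 20)

#' Ellipsoid volume cut-offs (-30% / +20%)
#'
#' For a prolate spheroid whose longest semi-axis carries the RECIST diameter,
#' a change along that axis alone changes the volume by the same percentage, so
#' the ellipsoid criterion keeps the RECIST percentages on the volume scale.
#' @return a [cutoff_set()].
#' @export
ellipsoid_cutoffs <- function() cutoff_set("ELLIPSOID", -30, 20)

#' Map diameter cut-offs to spherical-volume cut-offs (cube law)
#'
#' A diameter change of `c`% corresponds, for a sphere, to a volume change of
#' `100 * ((1 + c/100)^3 - 1)`%. RECIST's (-30, +20) maps to (-65.7, +72.8);
#' the -65.7% is often quoted rounded as a "65% volume reduction".
#'
#' @param recist a [cutoff_set()] of diameter cut-offs (default RECIST 1.1).
#' @return a `cutoff_set` on the volume scale, labelled `"SPHERE"`.
#' @export
derive_sphere_cutoffs <- function(recist = recist_cutoffs()) {
  cube <- function(pct) 100 * ((1 + pct / 100)^3 - 1)
  cutoff_set("SPHERE", cube(recist$pr_cutoff_pct), cube(recist$pd_cutoff_pct))
}

#' Spherical-volume cut-offs derived from RECIST (-65.7% / +72.8%)
#' @return a [cutoff_set()].
#' @export
sphere_cutoffs <- function() derive_sphere_cutoffs(recist_cutoffs())

#' Read or write a cut-off set as JSON
#'
#' Allows alternative volumetric cut-offs to be screened from a config file.
#' @param x a [cutoff_set()] (for writing).
#' @param path JSON file path.
#' @return `read_cutoffs` returns a `cutoff_set`; `write_cutoffs` returns
#'   `path` invisibly.
#' @export
write_cutoffs <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cutoffs
#' @export
read_cutoffs <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cutoff_set(obj$criteria, obj$pr_cutoff_pct, obj$pd_cutoff_pct)
}

.size_category <- function(change_pct, cutoffs, new_lesion) {
  if (new_lesion) return("PD")                       # overrides size-based PR
  if (change_pct <= cutoffs$pr_cutoff_pct) return("PR")
  if (change_pct >= cutoffs$pd_cutoff_pct) return("PD")
  "SD"
}

.check_same_assessment <- function(summary_t, summary_0) {
  if (summary_t$patient_id != summary_0$patient_id)
    stop("summaries belong to different patients")
  ids_t <- attr(summary_t, "lesion_ids")
  ids_0 <- attr(summary_0, "lesion_ids")
  if (!is.null(ids_t) && !is.null(ids_0) && !identical(ids_t, ids_0))
    stop("mismatched target sets: ",
         paste(ids_t, collapse = "+"), " vs ", paste(ids_0, collapse = "+"))
  if (is.null(ids_t) && summary_t$n_lesions != summary_0$n_lesions)
    stop("mismatched target sets (lesion counts differ)")
  invisible(TRUE)
}

.response_call <- function(summary_t, criteria, category, size_change_pct,
                           density_change_pct = NA_real_,
                           new_lesion = FALSE, new_nodule = FALSE,
                           density_missing = FALSE) {
  data.frame(patient_id = summary_t$patient_id,
             timepoint_months = summary_t$timepoint_months,
             criteria = criteria,
             category = category,
             size_change_pct = size_change_pct,
             density_change_pct = density_change_pct,
             new_lesion = new_lesion,
             new_nodule = new_nodule,
             density_missing = density_missing,
             stringsAsFactors = FALSE)
}

#' Classify response by RECIST 1.1 (sum of longest diameters)
#'
#' PR when the sum of diameters falls by at least 30% from baseline, PD when it
#' grows by at least 20% or a new lesion appears, SD otherwise.
#'
#' @param summary_t follow-up [summarize_timepoint()] row.
#' @param summary_0 baseline summary row for the same target set.
#' @param new_lesion has a new lesion appeared by this timepoint?
#' @return single-row response-call data frame.
#' @export
classify_recist <- function(summary_t, summary_0, new_lesion = FALSE) {
  .check_same_assessment(summary_t, summary_0)
  change <- relative_change(summary_0$sum_longest_diameter_mm,
                            summary_t$sum_longest_diameter_mm)
  .response_call(summary_t, "RECIST",
                 .size_category(change, recist_cutoffs(), new_lesion),
                 change, new_lesion = new_lesion)
}

#' Classify response from total target-lesion volume
#'
#' Applies a volumetric cut-off set (sphere-derived or ellipsoid) to the
#' relative change in total volume; a new lesion forces PD.
#'
#' @inheritParams classify_recist
#' @param cutoffs a [cutoff_set()] on the volume scale.
#' @return single-row response-call data frame.
#' @export
classify_volume <- function(summary_t, summary_0, cutoffs,
                            new_lesion = FALSE) {
  stopifnot(inherits(cutoffs, "cutoff_set"))
  .check_same_assessment(summary_t, summary_0)
  change <- relative_change(summary_0$total_volume_mL,
                            summary_t$total_volume_mL)
  .response_call(summary_t, cutoffs$criteria,
                 .size_category(change, cutoffs, new_lesion),
                 change, new_lesion = new_lesion)
}

#' Classify response by Choi criteria (size and CT density)
#'
#' PR: size decrease of at least 10% *or* mean lesion density decrease of at
#' least 15% (HU), with no new lesion or new intratumoral nodule. PD: new
#' lesion/nodule, or size increase of at least 10% without the density PR
#' condition. SD otherwise. If density change is unavailable the call proceeds
#' on size alone and is flagged `density_missing`.
#'
#' @inheritParams classify_recist
#' @param new_nodule new or growing intratumoral nodule?
#' @return single-row response-call data frame.
#' @export
classify_choi <- function(summary_t, summary_0, new_lesion = FALSE,
                          new_nodule = FALSE) {
  .check_same_assessment(summary_t, summary_0)
  size_change <- relative_change(summary_0$sum_longest_diameter_mm,
                                 summary_t$sum_longest_diameter_mm)
  dens_change <- summary_t$mean_relative_density_change_pct
  density_missing <- is.na(dens_change)
  dens_pr <- !density_missing && dens_change <= -15
  progression_event <- isTRUE(new_lesion) || isTRUE(new_nodule)
  category <- if (progression_event) {
    "PD"
  } else if (size_change <= -10 || dens_pr) {
    "PR"
  } else if (size_change >= 10 && !dens_pr) {
    "PD"
  } else {
    "SD"
  }
  .response_call(summary_t, "CHOI", category, size_change,
                 density_change_pct = if (density_missing) NA_real_ else dens_change,
                 new_lesion = new_lesion, new_nodule = new_nodule,
                 density_missing = density_missing)
}

#' Classify a raw size change against a symmetric threshold
#'
#' The unscaled 1D-vs-3D comparison asks whether each measure registers a
#' change of at least `threshold_pct` in either direction (boundary
#' inclusive).
#'
#' @param baseline positive baseline measurement.
#' @param value follow-up measurement.
#' @param threshold_pct positive detection threshold in percent (default 20).
#' @return list of class `change_class` with `direction` (one of
#'   `"DECREASE"`, `"NO_CHANGE"`, `"INCREASE"`), `change_pct`, `threshold_pct`.
#' @export
classify_size_change <- function(baseline, value, threshold_pct = 20) {
  stopifnot(threshold_pct > 0)
  change <- relative_change(baseline, value)
  direction <- if (change <= -threshold_pct) "DECREASE"
  else if (change >= threshold_pct) "INCREASE"
  else "NO_CHANGE"
  structure(list(direction = direction, change_pct = change,
                 threshold_pct = threshold_pct),
            class = "change_class")
}
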
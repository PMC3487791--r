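# Landmark survival analysis: Kaplan-Meier product-limit curves, the log-rank
# test (2 or 3 groups) and Mantel-Haenszel hazard ratios, all computed from
# first principles so the published formulas are the contract.

#' Build a landmark survival cohort from response calls
#'
#' Overall survival is measured from the landmark CT (3, 6 or 12 months after
#' treatment start), so patients who died or were censored on or before the
#' landmark are excluded; this avoids guarantee-time bias when grouping by the
#' response observed at the landmark. Patients without a response call at the
#' landmark are likewise excluded and counted.
#'
#' @param survival data frame with `patient_id`, `os_months_from_first_imatinib`,
#'   `event` (1 = death).
#' @param landmark_months landmark timepoint: 3, 6 or 12.
#' @param calls data frame with `patient_id` and `category` (PR/SD/PD) at the
#'   landmark.
#' @param grouping `"pd_vs_rest"` (PD vs SD+PR) or `"three_group"`.
#' @return data frame with `patient_id`, `time_months` (from the landmark),
#'   `event`, `group`; attributes `n_excluded_landmark` and `n_no_call` count
#'   exclusions.
#' @export
landmark_cohort <- function(survival, landmark_months, calls,
                            grouping = c("pd_vs_rest", "three_group")) {
  grouping <- match.arg(grouping)
  if (!landmark_months %in% c(3, 6, 12))
    stop("landmark must be 3, 6 or 12 months")
  calls <- calls[!duplicated(calls$patient_id), , drop = FALSE]
  idx <- match(survival$patient_id, calls$patient_id)
  no_call <- is.na(idx)
  category <- calls$category[idx]
  pre_landmark <- !no_call &
    survival$os_months_from_first_imatinib <= landmark_months
  keep <- !no_call & !pre_landmark
  group <- switch(grouping,
    pd_vs_rest = ifelse(category[keep] == "PD", "PD", "non-PD"),
    three_group = category[keep])
  out <- data.frame(
    patient_id = survival$patient_id[keep],
    time_months = survival$os_months_from_first_imatinib[keep] - landmark_months,
    event = as.integer(survival$event[keep]),
    group = group,
    stringsAsFactors = FALSE)
  attr(out, "n_excluded_landmark") <- sum(pre_landmark)
  attr(out, "n_no_call") <- sum(no_call)
  attr(out, "landmark_months") <- landmark_months
  out
}

#' Kaplan-Meier product-limit estimate
#'
#' Standard product-limit estimator; at tied times events are handled before
#' censorings (a subject censored at t is still at risk for events at t).
#'
#' @param time non-negative follow-up times.
#' @param event event indicators (1/TRUE = event, 0/FALSE = censored).
#' @return list of class `km_curve` with the per-event-time table (`time`,
#'   `n_risk`, `n_event`, `survival`), the sample size `n` and the KM `median`
#'   (NA if the curve never reaches 0.5).
#' @export
km_estimate <- function(time, event) {
  if (!length(time)) stop("need at least one record")
  if (length(event) != length(time)) stop("time and event lengths differ")
  if (any(time < 0)) stop("negative times")
  event <- as.integer(as.logical(event))
  times <- sort(unique(time[event == 1]))
  n_risk <- vapply(times, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(times, function(t) sum(time == t & event == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  med <- if (any(surv <= 0.5)) times[which(surv <= 0.5)[1]] else NA_real_
  structure(list(time = times, n_risk = n_risk, n_event = n_event,
                 survival = surv, n = length(time), median = med),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, %d event times, median = %s\n",
              x$n, length(x$time),
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' Export a Kaplan-Meier curve as a data frame
#'
#' @param x a `km_curve`.
#' @param truncate_months optional reporting truncation (rows beyond this time
#'   are dropped; estimation itself is untruncated).
#' @return data frame with `time`, `n_risk`, `n_event`, `survival`.
#' @export
km_table <- function(x, truncate_months = NULL) {
  stopifnot(inherits(x, "km_curve"))
  df <- data.frame(time = x$time, n_risk = x$n_risk, n_event = x$n_event,
                   survival = x$survival)
  if (!is.null(truncate_months)) df <- df[df$time <= truncate_months, ]
  df
}

# shared observed / expected / covariance machinery for log-rank and MH
.logrank_tables <- function(time, event, group) {
  group <- factor(group)
  g <- nlevels(group)
  O <- as.numeric(tapply(as.integer(event), group, sum, default = 0))
  E <- numeric(g)
  V <- matrix(0, g, g)
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n_j <- as.numeric(tapply(at_risk, group, sum, default = 0))
    n <- sum(n_j)
    d_j <- as.numeric(tapply(at_risk & time == t & event == 1, group, sum,
                             default = 0))
    d <- sum(d_j)
    if (n == 0 || d == 0) next
    E <- E + d * n_j / n
    if (n > 1) {
      w <- d * (n - d) / (n - 1)
      p <- n_j / n
      V <- V + w * (diag(p, g, g) - outer(p, p))
    }
  }
  list(levels = levels(group), observed = O, expected = E, covariance = V)
}

#' Log-rank test across 2 or more groups
#'
#' The usual (O - E)' V^-1 (O - E) statistic accumulated over event times,
#' referred to a chi-square with (number of groups - 1) degrees of freedom.
#'
#' @param time,event survival times and event indicators.
#' @param group group labels (2 or more non-empty groups).
#' @return list of class `logrank_test` with `chi2`, `df`, `p_value`,
#'   `observed`, `expected`, `groups`.
#' @export
logrank <- function(time, event, group) {
  group <- factor(group)
  group <- droplevels(group)
  if (nlevels(group) < 2) stop("need at least 2 non-empty groups")
  lt <- .logrank_tables(time, event, group)
  g <- length(lt$levels)
  u <- (lt$observed - lt$expected)[-g]
  Vm <- lt$covariance[-g, -g, drop = FALSE]
  chi2 <- tryCatch(as.numeric(t(u) %*% solve(Vm, u)),
                   error = function(e) {
                     # singular covariance (e.g. no overlap): generalised inverse
                     sv <- svd(Vm)
                     pos <- sv$d > max(sv$d) * 1e-10
                     vinv <- sv$v[, pos, drop = FALSE] %*%
                       diag(1 / sv$d[pos], sum(pos)) %*%
                       t(sv$u[, pos, drop = FALSE])
                     as.numeric(t(u) %*% vinv %*% u)
                   })
  chi2 <- max(chi2, 0)
  df <- g - 1
  structure(list(chi2 = chi2, df = df,
                 p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
                 observed = stats::setNames(lt$observed, lt$levels),
                 expected = stats::setNames(lt$expected, lt$levels),
                 groups = lt$levels),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4g on %d df, p = %.4g\n",
              x$chi2, x$df, x$p_value))
  invisible(x)
}

#' Mantel-Haenszel hazard ratio between two groups
#'
#' `HR = (O1/E1) / (O0/E0)` with observed and expected event counts from the
#' log-rank table; the 95% confidence interval is
#' `exp(log HR +/- 1.96 * sqrt(1/E1 + 1/E0))`. Group 1 is the non-reference
#' group, so `HR > 1` means a higher hazard than the reference.
#'
#' @param time,event survival times and event indicators.
#' @param group labels with exactly two levels.
#' @param reference reference group label (defaults to the first factor level).
#' @return list of class `hazard_ratio` with `hr`, `ci_low`, `ci_high`,
#'   `logrank_chi2`, `logrank_p`, `reference`, `comparison`, and
#'   `ci_undefined` (TRUE when an expected count is zero).
#' @export
mh_hazard_ratio <- function(time, event, group, reference = NULL) {
  group <- droplevels(factor(group))
  if (nlevels(group) != 2) stop("exactly 2 groups required")
  if (is.null(reference)) reference <- levels(group)[1]
  if (!reference %in% levels(group)) stop("unknown reference group")
  group <- stats::relevel(group, ref = reference)
  lt <- .logrank_tables(time, event, group)
  O <- lt$observed; E <- lt$expected
  ci_undefined <- any(E == 0)
  if (ci_undefined) {
    hr <- NA_real_; ci <- c(NA_real_, NA_real_)
    warning("zero expected events in a group: hazard ratio undefined")
  } else {
    hr <- (O[2] / E[2]) / (O[1] / E[1])
    se <- sqrt(1 / E[1] + 1 / E[2])
    ci <- hr * exp(c(-1.96, 1.96) * se)
  }
  lr <- logrank(time, event, group)
  structure(list(hr = unname(hr), ci_low = unname(ci[1]),
                 ci_high = unname(ci[2]),
                 logrank_chi2 = lr$chi2, logrank_p = lr$p_value,
                 reference = reference,
                 comparison = lt$levels[2],
                 observed = stats::setNames(O, lt$levels),
                 expected = stats::setNames(E, lt$levels),
                 ci_undefined = ci_undefined),
            class = "hazard_ratio")
}

#' @export
print.hazard_ratio <- function(x, ...) {
  cat(sprintf("Mantel-Haenszel HR (%s vs %s): %.3f [%.3f, %.3f]\n",
              x$comparison, x$reference, x$hr, x$ci_low, x$ci_high))
  cat(sprintf("  log-rank chi-square = %.4g, p = %.4g\n",
              x$logrank_chi2, x$logrank_p))
  invisible(x)
}
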
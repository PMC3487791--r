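# Synthetic cohort generator: prolate-spheroid liver lesions evolving under
# per-class anisotropic multiplicative axis rates, with reader and method
# measurement noise at the levels reported for manual/semi-automated CT
# volumetry, density decline in responders, and response-linked survival.

.SIM_CLASSES <- c("isotropic_responder", "anisotropic_responder",
                  "stable", "progressor")

#' Configuration for the synthetic GIST liver-metastasis cohort
#'
#' Defaults encode the stated world: lesions are prolate spheroids (two short
#' semi-axes equal, the longest carries the RECIST diameter); each patient
#' belongs to a latent class whose per-quarter multiplicative axis rates drive
#' anisotropic or isotropic shrinkage/growth; measurement noise is
#' multiplicative log-normal calibrated so that the mean absolute relative
#' difference between two readers (methods) matches the reported 0.2%/3.2%
#' (0.15%/9.6%) for 1D/3D; responders' CT density declines; survival is
#' exponential per class with uniform censoring.
#'
#' @param n_patients cohort size.
#' @param seed RNG seed; seeded runs are bit-reproducible.
#' @param lesions_per_patient integer vector sampled uniformly.
#' @param baseline_r3_meanlog,baseline_r3_sdlog log-normal parameters of the
#'   longest baseline semi-axis (mm; default median 20 mm).
#' @param baseline_aspect_range range of the short/long axis ratio in (0, 1].
#' @param class_probs named probabilities of the four latent classes.
#' @param axis_step_rates per-class multiplicative per-quarter (3-month) rates
#'   for the three semi-axes (ascending order).
#' @param density_baseline_mean_HU,density_baseline_sd_HU baseline mean lesion
#'   density (Hounsfield units).
#' @param density_step_factor per-class per-quarter multiplicative density
#'   factor (responders decline).
#' @param reader_variability_1d_pct,reader_variability_3d_pct inter-reader
#'   mean absolute relative difference, percent (1D diameters / 3D volumes).
#' @param method_variability_1d_pct,method_variability_3d_pct manual vs
#'   semi-automated variability, percent.
#' @param density_noise_sd_HU additive HU measurement noise.
#' @param os_median_months per-class median overall survival (months from
#'   first dose).
#' @param censor_range_months uniform censoring window (months).
#' @param new_lesion_prob per-timepoint probability that a progressor develops
#'   a new lesion (cumulative once appeared).
#' @param timepoints_months measurement schedule, baseline first.
#' @param scan_jitter_months uniform jitter of actual scan dates around the
#'   nominal timepoints.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(
    n_patients = 56L,
    seed = 20121102L,
    lesions_per_patient = 1:4,
    baseline_r3_meanlog = log(20),
    baseline_r3_sdlog = 0.45,
    baseline_aspect_range = c(0.55, 1),
    class_probs = c(isotropic_responder = 0.10,
                    anisotropic_responder = 0.45,
                    stable = 0.35,
                    progressor = 0.10),
    axis_step_rates = list(
      isotropic_responder = c(0.85, 0.85, 0.85),
      anisotropic_responder = c(0.75, 0.75, 0.93),
      stable = c(1, 1, 1),
      progressor = c(1.25, 1.25, 1.25)),
    density_baseline_mean_HU = 75,
    density_baseline_sd_HU = 12,
    density_step_factor = c(isotropic_responder = 0.80,
                            anisotropic_responder = 0.80,
                            stable = 1.00,
                            progressor = 1.02),
    reader_variability_1d_pct = 0.2,
    reader_variability_3d_pct = 3.2,
    method_variability_1d_pct = 0.15,
    method_variability_3d_pct = 9.6,
    density_noise_sd_HU = 3,
    os_median_months = c(isotropic_responder = 66,
                         anisotropic_responder = 66,
                         stable = 48,
                         progressor = 16),
    censor_range_months = c(36, 110),
    new_lesion_prob = 0.30,
    timepoints_months = c(0L, 3L, 6L, 12L),
    scan_jitter_months = 0.4) {
  cfg <- list(n_patients = as.integer(n_patients), seed = as.integer(seed),
              lesions_per_patient = as.integer(lesions_per_patient),
              baseline_r3_meanlog = baseline_r3_meanlog,
              baseline_r3_sdlog = baseline_r3_sdlog,
              baseline_aspect_range = baseline_aspect_range,
              class_probs = class_probs,
              axis_step_rates = axis_step_rates,
              density_baseline_mean_HU = density_baseline_mean_HU,
              density_baseline_sd_HU = density_baseline_sd_HU,
              density_step_factor = density_step_factor,
              reader_variability_1d_pct = reader_variability_1d_pct,
              reader_variability_3d_pct = reader_variability_3d_pct,
              method_variability_1d_pct = method_variability_1d_pct,
              method_variability_3d_pct = method_variability_3d_pct,
              density_noise_sd_HU = density_noise_sd_HU,
              os_median_months = os_median_months,
              censor_range_months = censor_range_months,
              new_lesion_prob = new_lesion_prob,
              timepoints_months = as.integer(timepoints_months),
              scan_jitter_months = scan_jitter_months)
  .validate_sim_config(cfg)
  structure(cfg, class = "simulation_config")
}

.validate_sim_config <- function(cfg) {
  if (cfg$n_patients < 1) stop("n_patients must be >= 1")
  if (any(cfg$lesions_per_patient < 1)) stop("lesions_per_patient must be >= 1")
  if (!setequal(names(cfg$class_probs), .SIM_CLASSES))
    stop("class_probs must be named by: ", paste(.SIM_CLASSES, collapse = ", "))
  if (any(cfg$class_probs < 0) || abs(sum(cfg$class_probs) - 1) > 1e-8)
    stop("class_probs must be non-negative and sum to 1")
  for (nm in .SIM_CLASSES) {
    r <- cfg$axis_step_rates[[nm]]
    if (is.null(r) || length(r) != 3 || any(r <= 0))
      stop("axis_step_rates[['", nm, "']] must be 3 positive rates")
  }
  if (!setequal(names(cfg$density_step_factor), .SIM_CLASSES) ||
      any(cfg$density_step_factor <= 0))
    stop("density_step_factor must be positive and named by class")
  if (!setequal(names(cfg$os_median_months), .SIM_CLASSES) ||
      any(cfg$os_median_months <= 0))
    stop("os_median_months must be positive and named by class")
  noise <- c(cfg$reader_variability_1d_pct, cfg$reader_variability_3d_pct,
             cfg$method_variability_1d_pct, cfg$method_variability_3d_pct)
  if (any(noise < 0)) stop("variability percentages must be >= 0")
  if (cfg$new_lesion_prob < 0 || cfg$new_lesion_prob > 1)
    stop("new_lesion_prob must be in [0, 1]")
  if (cfg$timepoints_months[1] != 0 || any(diff(cfg$timepoints_months) <= 0))
    stop("timepoints_months must start at 0 and increase")
  if (any(cfg$timepoints_months %% 3 != 0))
    stop("timepoints_months must be multiples of 3 (quarterly rate steps)")
  invisible(TRUE)
}

# log-scale sd such that |a - b| / mid has the given mean for two series each
# carrying an independent N(0, sd) log error (split = 2), or one series
# carrying the whole offset (split = 1): E|N(0, s)| = s * sqrt(2/pi)
.noise_sd <- function(variability_pct, split = 2) {
  (variability_pct / 100) * sqrt(pi / 2) / sqrt(split)
}

.sorted_axes <- function(r1, r2, r3) {
  m <- cbind(r1, r2, r3)
  t(apply(m, 1, sort))
}

#' Simulate a measurement cohort
#'
#' Draws a cohort under the configured stated world and returns the four
#' tables of the cohort schema plus the latent truth. Measured diameters track
#' the longest semi-axis (re-sorted each timepoint, as a radiologist measures
#' the current longest diameter); measured volumes carry multiplicative
#' log-normal noise; the emitted semi-axes are the true axes rescaled
#' isotropically to match the measured volume exactly, so every row passes the
#' axis/volume consistency invariant. Manual measurements are made by two
#' readers (R1, R2); the semi-automated method is a single deterministic
#' "reader" (S1) carrying the inter-method offset, and only semi-automated
#' rows carry densities.
#'
#' @param config a [simulation_config()].
#' @return list of class `synthetic_cohort` with data frames `measurements`,
#'   `scans`, `survival`, `truth` and the `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  .validate_sim_config(config)
  set.seed(config$seed)
  cfg <- config
  n <- cfg$n_patients
  tps <- cfg$timepoints_months
  pid <- sprintf("P%03d", seq_len(n))
  cls <- sample(names(cfg$class_probs), n, replace = TRUE,
                prob = cfg$class_probs)

  # lesions at baseline (prolate spheroid: r1 = r2 = aspect * r3)
  n_les <- sample(cfg$lesions_per_patient, n, replace = TRUE)
  les <- data.frame(
    patient_id = rep(pid, n_les),
    true_class = rep(cls, n_les),
    stringsAsFactors = FALSE)
  les$lesion_id <- unlist(lapply(n_les, function(k) sprintf("L%d", seq_len(k))))
  m <- nrow(les)
  les$r3_0 <- stats::rlnorm(m, cfg$baseline_r3_meanlog, cfg$baseline_r3_sdlog)
  aspect <- stats::runif(m, cfg$baseline_aspect_range[1],
                         cfg$baseline_aspect_range[2])
  les$r1_0 <- les$r2_0 <- aspect * les$r3_0
  les$density_0 <- stats::rnorm(m, cfg$density_baseline_mean_HU,
                                cfg$density_baseline_sd_HU)

  # lesion state per timepoint
  rate_mat <- do.call(rbind, cfg$axis_step_rates[les$true_class])
  truth_list <- lapply(tps, function(tp) {
    steps <- tp / 3
    ax <- .sorted_axes(les$r1_0 * rate_mat[, 1]^steps,
                       les$r2_0 * rate_mat[, 2]^steps,
                       les$r3_0 * rate_mat[, 3]^steps)
    data.frame(patient_id = les$patient_id,
               lesion_id = les$lesion_id,
               true_class = les$true_class,
               timepoint_months = tp,
               r1_mm = ax[, 1], r2_mm = ax[, 2], r3_mm = ax[, 3],
               true_volume_mL = ellipsoid_volume(ax[, 1], ax[, 2], ax[, 3]) /
                 MM3_PER_ML,
               true_density_HU = les$density_0 *
                 cfg$density_step_factor[les$true_class]^steps,
               stringsAsFactors = FALSE)
  })
  truth <- do.call(rbind, truth_list)
  rownames(truth) <- NULL

  # new-lesion flags: progressors only, Bernoulli per follow-up, persistent
  new_flag <- matrix(FALSE, n, length(tps),
                     dimnames = list(pid, as.character(tps)))
  prog <- cls == "progressor"
  if (any(prog) && length(tps) > 1) {
    draws <- matrix(stats::runif(sum(prog) * (length(tps) - 1)) <
                      cfg$new_lesion_prob, nrow = sum(prog))
    cum <- t(apply(draws, 1, cummax))
    new_flag[prog, -1] <- cum == 1
  }

  # measurements: manual readers R1/R2 + semi-automated S1
  arms <- data.frame(method = c("manual", "manual", "semiauto"),
                     reader_id = c("R1", "R2", "S1"),
                     stringsAsFactors = FALSE)
  sd_r1 <- .noise_sd(cfg$reader_variability_1d_pct, split = 2)
  sd_r3 <- .noise_sd(cfg$reader_variability_3d_pct, split = 2)
  sd_m1 <- .noise_sd(cfg$method_variability_1d_pct, split = 1)
  sd_m3 <- .noise_sd(cfg$method_variability_3d_pct, split = 1)
  meas_list <- lapply(seq_len(nrow(arms)), function(i) {
    semi <- arms$method[i] == "semiauto"
    nr <- nrow(truth)
    eps1 <- if (semi) stats::rnorm(nr, 0, sd_m1) else stats::rnorm(nr, 0, sd_r1)
    eps3 <- if (semi) stats::rnorm(nr, 0, sd_m3) else stats::rnorm(nr, 0, sd_r3)
    vol <- truth$true_volume_mL * exp(eps3)
    scale <- (vol / truth$true_volume_mL)^(1 / 3)
    dens <- if (semi)
      truth$true_density_HU + stats::rnorm(nr, 0, cfg$density_noise_sd_HU)
    else NA_real_
    data.frame(patient_id = truth$patient_id,
               lesion_id = truth$lesion_id,
               timepoint_months = truth$timepoint_months,
               method = arms$method[i],
               reader_id = arms$reader_id[i],
               longest_diameter_mm = 2 * truth$r3_mm * exp(eps1),
               volume_mL = vol,
               mean_density_HU = dens,
               r1_mm = truth$r1_mm * scale,
               r2_mm = truth$r2_mm * scale,
               r3_mm = truth$r3_mm * scale,
               new_lesion = new_flag[cbind(truth$patient_id,
                                           as.character(truth$timepoint_months))],
               new_nodule = FALSE,
               stringsAsFactors = FALSE)
  })
  measurements <- do.call(rbind, meas_list)
  ord <- order(measurements$patient_id, measurements$lesion_id,
               measurements$timepoint_months, measurements$method,
               measurements$reader_id)
  measurements <- measurements[ord, , drop = FALSE]
  rownames(measurements) <- NULL

  # scans: one per patient-timepoint, jittered around the nominal month
  scan_grid <- expand.grid(patient_id = pid, nominal = tps,
                           stringsAsFactors = FALSE)
  jitter <- ifelse(scan_grid$nominal == 0, 0,
                   stats::runif(nrow(scan_grid), -cfg$scan_jitter_months,
                                cfg$scan_jitter_months))
  scans <- data.frame(
    patient_id = scan_grid$patient_id,
    scan_date = as.Date("2005-01-01") +
      round((scan_grid$nominal + jitter) * 30.44),
    months_from_first_imatinib = scan_grid$nominal + jitter,
    stringsAsFactors = FALSE)
  scans <- scans[order(scans$patient_id, scans$months_from_first_imatinib), ]
  rownames(scans) <- NULL

  # survival: exponential per class, uniform censoring
  hazard <- log(2) / cfg$os_median_months[cls]
  death <- stats::rexp(n, rate = hazard)
  censor <- stats::runif(n, cfg$censor_range_months[1],
                         cfg$censor_range_months[2])
  survival <- data.frame(
    patient_id = pid,
    os_months_from_first_imatinib = pmin(death, censor),
    event = as.integer(death <= censor),
    stringsAsFactors = FALSE)

  structure(list(measurements = measurements, scans = scans,
                 survival = survival, truth = truth, config = cfg),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients, %d lesions, %d measurement rows\n",
              x$config$n_patients,
              length(unique(paste(x$truth$patient_id, x$truth$lesion_id))),
              nrow(x$measurements)))
  print(table(x$truth$true_class[!duplicated(x$truth$patient_id)]))
  invisible(x)
}

#' Expected per-class 1D/3D detection probabilities
#'
#' Analytic oracle for recovery tests: from the configured axis rates, the
#' true diameter ratio at t months is the largest-axis ratio and the true
#' volume ratio the product of the three axis ratios. Detection of a >=
#' `threshold_pct` change by a single reader at both scans adds a log-normal
#' error with variance `2 * sd^2`, so the detection probability is a normal
#' tail probability (an indicator under zero noise). The representative
#' baseline aspect is the midpoint of `baseline_aspect_range` (it only matters
#' if axis re-sorting flips the longest axis).
#'
#' @param config a [simulation_config()].
#' @param threshold_pct detection threshold (default 20).
#' @return list with `per_class` (one row per class and follow-up timepoint,
#'   with decrease/increase/any detection probabilities for 1D and 3D) and
#'   `cohort` (class-probability-weighted rates per timepoint).
#' @export
expected_detection_rates <- function(config, threshold_pct = 20) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  tps <- setdiff(cfg$timepoints_months, 0L)
  a <- mean(cfg$baseline_aspect_range)
  sd1 <- .noise_sd(cfg$reader_variability_1d_pct, split = 2) * sqrt(2)
  sd3 <- .noise_sd(cfg$reader_variability_3d_pct, split = 2) * sqrt(2)
  lo <- log(1 - threshold_pct / 100)
  hi <- log(1 + threshold_pct / 100)
  p_tail <- function(ratio, sd, side) {
    if (sd == 0) {
      if (side == "dec") as.numeric(ratio <= 1 - threshold_pct / 100)
      else as.numeric(ratio >= 1 + threshold_pct / 100)
    } else if (side == "dec") {
      stats::pnorm(lo - log(ratio), 0, sd)
    } else {
      stats::pnorm(hi - log(ratio), 0, sd, lower.tail = FALSE)
    }
  }
  rows <- list()
  for (cl in .SIM_CLASSES) {
    rates <- cfg$axis_step_rates[[cl]]
    for (tp in tps) {
      steps <- tp / 3
      ax0 <- c(a, a, 1)
      axt <- ax0 * rates^steps
      d_ratio <- max(axt) / max(ax0)
      v_ratio <- prod(rates)^steps
      rows[[length(rows) + 1]] <- data.frame(
        true_class = cl, timepoint_months = tp,
        diameter_ratio = d_ratio, volume_ratio = v_ratio,
        p_decrease_1d = p_tail(d_ratio, sd1, "dec"),
        p_increase_1d = p_tail(d_ratio, sd1, "inc"),
        p_decrease_3d = p_tail(v_ratio, sd3, "dec"),
        p_increase_3d = p_tail(v_ratio, sd3, "inc"),
        stringsAsFactors = FALSE)
    }
  }
  per_class <- do.call(rbind, rows)
  per_class$p_detect_1d <- per_class$p_decrease_1d + per_class$p_increase_1d
  per_class$p_detect_3d <- per_class$p_decrease_3d + per_class$p_increase_3d
  w <- cfg$class_probs[per_class$true_class]
  agg <- stats::aggregate(
    cbind(p_decrease_1d, p_increase_1d, p_detect_1d,
          p_decrease_3d, p_increase_3d, p_detect_3d) * w ~ timepoint_months,
    data = cbind(per_class, w = unname(w)), FUN = sum)
  names(agg) <- sub("^cbind.*\\.", "", names(agg))
  list(per_class = per_class, cohort = agg)
}

#' Simulate paired measurements at a stated method variability
#'
#' Generates pairs `(a, b)` with `b = a * exp(delta)`,
#' `delta ~ N(0, (v/100) * sqrt(pi/2))`, so the mean absolute relative
#' difference (the Bland-Altman relative variability) equals `v` percent in
#' expectation. Used to check that the agreement statistics recover a known
#' variability.
#'
#' @param true_values positive underlying measurements.
#' @param variability_pct target mean absolute relative difference (percent).
#' @return data frame with columns `a` and `b`.
#' @export
simulate_paired_measurements <- function(true_values, variability_pct) {
  stopifnot(all(true_values > 0), variability_pct >= 0)
  delta <- stats::rnorm(length(true_values), 0,
                        .noise_sd(variability_pct, split = 1))
  data.frame(a = true_values, b = true_values * exp(delta))
}

#' Write / read a cohort as a directory of CSV files
#'
#' `write_cohort_dir` emits `measurements.csv`, `scans.csv`, `survival.csv`
#' and (for synthetic cohorts) `truth.csv`; `read_cohort_dir` re-reads and
#' validates them through [read_cohort()].
#'
#' @param cohort a `synthetic_cohort` or a list with the same data frames.
#' @param dir target directory (created if needed).
#' @return `write_cohort_dir`: `dir`, invisibly. `read_cohort_dir`: list with
#'   `measurements`, `scans`, `survival` (validated records) and `truth` when
#'   present.
#' @export
write_cohort_dir <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_cohort(cohort$measurements, file.path(dir, "measurements.csv"))
  write_cohort(cohort$scans, file.path(dir, "scans.csv"))
  write_cohort(cohort$survival, file.path(dir, "survival.csv"))
  if (!is.null(cohort$truth))
    utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                     row.names = FALSE, na = "")
  invisible(dir)
}

#' @rdname write_cohort_dir
#' @export
read_cohort_dir <- function(dir) {
  out <- list(
    measurements = read_cohort(file.path(dir, "measurements.csv"),
                               "measurements")$records,
    scans = read_cohort(file.path(dir, "scans.csv"), "scans")$records,
    survival = read_cohort(file.path(dir, "survival.csv"),
                           "survival")$records)
  truth_path <- file.path(dir, "truth.csv")
  if (file.exists(truth_path))
    out$truth <- utils::read.csv(truth_path, stringsAsFactors = FALSE)
  out
}
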
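test_that("simulation_config validates before any sampling", {
  expect_error(simulation_config(class_probs = c(isotropic_responder = 0.5,
                                                 anisotropic_responder = 0.5,
                                                 stable = 0.5,
                                                 progressor = 0.5)), "sum to 1")
  expect_error(simulation_config(axis_step_rates = list(
    isotropic_responder = c(0.9, 0.9),
    anisotropic_responder = c(0.75, 0.75, 0.93),
    stable = c(1, 1, 1), progressor = c(1.25, 1.25, 1.25))), "3 positive")
  expect_error(simulation_config(n_patients = 0), "n_patients")
  expect_error(simulation_config(new_lesion_prob = 1.4), "new_lesion_prob")
  expect_error(simulation_config(timepoints_months = c(0, 4, 8)), "multiples of 3")
})

test_that("same seed gives bit-identical cohorts; different seeds differ", {
  a <- simulate_cohort(quick_config())
  b <- simulate_cohort(quick_config())
  expect_identical(a$measurements, b$measurements)
  expect_identical(a$survival, b$survival)
  expect_identical(a$truth, b$truth)
  c <- simulate_cohort(simulation_config(n_patients = 40, seed = 12))
  expect_false(identical(a$measurements$volume_mL, c$measurements$volume_mL))
})

test_that("all-stable zero-noise cohort is constant across timepoints", {
  cfg <- zero_noise_config(
    n_patients = 15, seed = 3,
    class_probs = c(isotropic_responder = 0, anisotropic_responder = 0,
                    stable = 1, progressor = 0))
  co <- simulate_cohort(cfg)
  m <- co$measurements
  base <- m[m$timepoint_months == 0, ]
  key <- function(d) paste(d$patient_id, d$lesion_id, d$method, d$reader_id)
  for (tp in c(3, 6, 12)) {
    mt <- m[m$timepoint_months == tp, ]
    idx <- match(key(mt), key(base))
    expect_equal(mt$longest_diameter_mm, base$longest_diameter_mm[idx])
    expect_equal(mt$volume_mL, base$volume_mL[idx])
  }
})

test_that("anisotropic shrinkage yields 3D-detected, 1D-missed decreases at 3 months", {
  cfg <- zero_noise_config(
    n_patients = 12, seed = 5,
    class_probs = c(isotropic_responder = 0, anisotropic_responder = 1,
                    stable = 0, progressor = 0))
  co <- simulate_cohort(cfg)
  # per-quarter rates (0.75, 0.75, 0.93): volume -47.7%, diameter -7%
  tr0 <- co$truth[co$truth$timepoint_months == 0, ]
  tr3 <- co$truth[co$truth$timepoint_months == 3, ]
  expect_equal(tr3$true_volume_mL / tr0$true_volume_mL,
               rep(0.75 * 0.75 * 0.93, nrow(tr0)), tolerance = 1e-12)
  expect_equal(tr3$r3_mm / tr0$r3_mm, rep(0.93, nrow(tr0)), tolerance = 1e-12)
  cd <- run_change_detection(co$measurements)
  tab3 <- cd[["3"]]$table
  expect_equal(tab3["NO_CHANGE", "DECREASE"], 12)
  expect_equal(sum(tab3) - tab3["NO_CHANGE", "DECREASE"], 0)
})

test_that("expected_detection_rates matches the configured axis rates analytically", {
  cfg <- zero_noise_config(axis_step_rates = list(
    isotropic_responder = c(0.9, 0.9, 0.9),
    anisotropic_responder = c(0.75, 0.75, 0.93),
    stable = c(1, 1, 1),
    progressor = c(1.25, 1.25, 1.25)))
  er <- expected_detection_rates(cfg)$per_class
  iso3 <- er[er$true_class == "isotropic_responder" & er$timepoint_months == 3, ]
  expect_equal(iso3$volume_ratio, 0.9^3)        # -27.1%: 3D detects
  expect_equal(iso3$p_decrease_3d, 1)
  expect_equal(iso3$p_detect_1d, 0)             # -10%: 1D does not
  stab <- er[er$true_class == "stable", ]
  expect_equal(sum(stab$p_detect_1d, stab$p_detect_3d), 0)
  prog3 <- er[er$true_class == "progressor" & er$timepoint_months == 3, ]
  expect_equal(prog3$p_increase_1d, 1)          # +25% on both scales
  expect_equal(prog3$p_increase_3d, 1)
})

test_that("spherical lesions under isotropic rates: sphere calls equal RECIST calls", {
  cfg <- zero_noise_config(
    n_patients = 60, seed = 9,
    baseline_aspect_range = c(1, 1),
    class_probs = c(isotropic_responder = 0.3, anisotropic_responder = 0,
                    stable = 0.4, progressor = 0.3),
    axis_step_rates = list(isotropic_responder = c(0.85, 0.85, 0.85),
                           anisotropic_responder = c(1, 1, 1),
                           stable = c(1, 1, 1),
                           progressor = c(1.25, 1.25, 1.25)))
  co <- simulate_cohort(cfg)
  calls <- classify_cohort(co$measurements, c("RECIST", "SPHERE"))
  wide <- merge(calls[calls$criteria == "RECIST",
                      c("patient_id", "timepoint_months", "category")],
                calls[calls$criteria == "SPHERE",
                      c("patient_id", "timepoint_months", "category")],
                by = c("patient_id", "timepoint_months"))
  expect_gt(nrow(wide), 0)
  expect_identical(wide$category.x, wide$category.y)
})

test_that("a larger anisotropic share raises the 1D-missed / 3D-detected cell", {
  shares <- c(0.2, 0.45, 0.7)
  expected_cell <- vapply(shares, function(s) {
    cfg <- simulation_config(class_probs = c(
      isotropic_responder = 0.10, anisotropic_responder = s,
      stable = 0.80 - s, progressor = 0.10))
    er <- expected_detection_rates(cfg)$per_class
    er3 <- er[er$timepoint_months == 3, ]
    w <- cfg$class_probs[er3$true_class]
    sum(w * (1 - er3$p_detect_1d) * er3$p_decrease_3d)
  }, numeric(1))
  expect_true(all(diff(expected_cell) > 0))

  # simulated counts follow the analytic trend (fixed seeds, n = 150)
  observed <- vapply(seq_along(shares), function(i) {
    cfg <- simulation_config(n_patients = 150, seed = 30 + i, class_probs = c(
      isotropic_responder = 0.10, anisotropic_responder = shares[i],
      stable = 0.80 - shares[i], progressor = 0.10))
    cd <- run_change_detection(simulate_cohort(cfg)$measurements)
    cd[["3"]]$table["NO_CHANGE", "DECREASE"] / cd[["3"]]$n
  }, numeric(1))
  expect_true(all(diff(observed) > 0))
})

test_that("truth table is exactly consistent with the ellipsoid volume formula", {
  co <- simulate_cohort(quick_config())
  expect_equal(co$truth$true_volume_mL,
               ellipsoid_volume(co$truth$r1_mm, co$truth$r2_mm,
                                co$truth$r3_mm) / 1000,
               tolerance = 1e-12)
  expect_true(all(co$truth$r1_mm <= co$truth$r2_mm &
                    co$truth$r2_mm <= co$truth$r3_mm))
  # survival table sane: non-negative times, 0/1 events, one row per patient
  expect_equal(nrow(co$survival), co$config$n_patients)
  expect_true(all(co$survival$os_months_from_first_imatinib >= 0))
  expect_true(all(co$survival$event %in% 0:1))
})
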
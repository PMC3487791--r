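test_that("read_cohort parses valid measurement rows and rejects invariant violations", {
  rows <- rbind(
    make_measurement("P1", "L1", 0, longest_diameter_mm = 30, volume_mL = 14.1),
    make_measurement("P1", "L2", 0, longest_diameter_mm = 20, volume_mL = 4.2),
    make_measurement("P2", "L1", 3, longest_diameter_mm = 25, volume_mL = 8))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(rows, path)
  io <- read_cohort(path, "measurements")
  expect_equal(io$report$n_accepted, 3)
  expect_equal(io$report$n_rejected, 0)
  expect_equal(io$records$longest_diameter_mm, c(30, 20, 25))

  bad <- rbind(rows,
               make_measurement("P3", "L1", 0, volume_mL = 0),
               make_measurement("P3", "L2", 5, volume_mL = 3),
               make_measurement("P3", "L3", 0, longest_diameter_mm = -1))
  write_cohort(bad, path)
  io <- read_cohort(path, "measurements")
  expect_equal(io$report$n_accepted, 3)
  expect_equal(io$rejected$row, c(4, 5, 6))
  expect_match(io$rejected$reason[1], "non-positive volume")
  expect_match(io$rejected$reason[2], "timepoint")
  expect_match(io$rejected$reason[3], "non-positive diameter")
})

test_that("read_cohort enforces the schema header and axis/volume consistency", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,lesion_id,timepoint_months",
               "P1,L1,0"), path)
  expect_error(read_cohort(path, "measurements"), "missing required column")

  # consistent prolate spheroid: V = 4/3 pi * 10 * 10 * 15 mm^3 = 6.2832 mL
  good_v <- ellipsoid_volume(10, 10, 15) / 1000
  rows <- rbind(
    make_measurement("P1", "L1", 0, longest_diameter_mm = 30,
                     volume_mL = good_v, r1_mm = 10, r2_mm = 10, r3_mm = 15),
    make_measurement("P1", "L2", 0, longest_diameter_mm = 30,
                     volume_mL = good_v * 1.01, r1_mm = 10, r2_mm = 10,
                     r3_mm = 15),
    make_measurement("P1", "L3", 0, longest_diameter_mm = 30,
                     volume_mL = good_v, r1_mm = 15, r2_mm = 10, r3_mm = 10))
  write_cohort(rows, path)
  io <- read_cohort(path, "measurements")
  expect_equal(io$report$n_accepted, 1)
  expect_match(io$rejected$reason[1], "inconsistent with volume")
  expect_match(io$rejected$reason[2], "ascending")
})

test_that("write_cohort / read_cohort round-trips a synthetic cohort", {
  cohort <- simulate_cohort(quick_config())
  dir <- withr::local_tempdir()
  write_cohort_dir(cohort, dir)
  back <- read_cohort_dir(dir)
  expect_equal(back$measurements, cohort$measurements, tolerance = 1e-12)
  expect_equal(back$survival, cohort$survival, tolerance = 1e-12)
  expect_equal(back$scans$months_from_first_imatinib,
               cohort$scans$months_from_first_imatinib, tolerance = 1e-12)
  # every simulated row satisfies the cohort invariants
  io <- read_cohort(file.path(dir, "measurements.csv"), "measurements")
  expect_equal(io$report$n_rejected, 0)
})

test_that("assign_timepoint picks the closest scan with earlier-tie rule and window", {
  scans <- data.frame(patient_id = "P1",
                      scan_date = as.Date("2005-01-01") + c(85, 113),
                      months_from_first_imatinib = c(2.8, 3.7))
  expect_equal(assign_timepoint(scans, 3)$months_from_first_imatinib, 2.8)
  scans$months_from_first_imatinib <- c(2.5, 3.5)
  expect_equal(assign_timepoint(scans, 3)$months_from_first_imatinib, 2.5)
  scans <- scans[1, ]; scans$months_from_first_imatinib <- 8.0
  expect_null(assign_timepoint(scans, 3))
  expect_null(assign_timepoint(scans[0, ], 6))
  expect_error(assign_timepoint(scans, 4), "3, 6 or 12")
})

test_that("select_target_lesions takes the two largest, ties by id, order-invariant", {
  base <- rbind(
    make_measurement("P1", "A", 0, longest_diameter_mm = 40),
    make_measurement("P1", "B", 0, longest_diameter_mm = 25),
    make_measurement("P1", "C", 0, longest_diameter_mm = 60))
  expect_equal(select_target_lesions(base)$lesion_ids, c("C", "A"))
  expect_equal(select_target_lesions(base[c(3, 1, 2), ])$lesion_ids, c("C", "A"))
  expect_equal(select_target_lesions(
    make_measurement("P1", "A", 0, longest_diameter_mm = 12))$lesion_ids, "A")
  tie <- rbind(
    make_measurement("P1", "A", 0, longest_diameter_mm = 30),
    make_measurement("P1", "B", 0, longest_diameter_mm = 30),
    make_measurement("P1", "C", 0, longest_diameter_mm = 10))
  expect_equal(select_target_lesions(tie)$lesion_ids, c("A", "B"))
  expect_error(select_target_lesions(base[0, ]), "no baseline lesions")
})

test_that("summarize_timepoint sums sizes, averages per-lesion density change, flags missing targets", {
  m <- rbind(
    make_measurement("P1", "L1", 3, longest_diameter_mm = 30, volume_mL = 14.1,
                     mean_density_HU = 70),
    make_measurement("P1", "L2", 3, longest_diameter_mm = 20, volume_mL = 4.2,
                     mean_density_HU = 68))
  base <- rbind(
    make_measurement("P1", "L1", 0, mean_density_HU = 100),
    make_measurement("P1", "L2", 0, mean_density_HU = 80))
  s <- summarize_timepoint(m, baseline = base, target = c("L1", "L2"))
  expect_equal(s$sum_longest_diameter_mm, 50)
  expect_equal(s$total_volume_mL, 18.3)
  expect_equal(s$mean_relative_density_change_pct, mean(c(-30, -15)))
  # permutation invariance
  s2 <- summarize_timepoint(m[2:1, ], baseline = base, target = c("L2", "L1"))
  expect_equal(s2$sum_longest_diameter_mm, s$sum_longest_diameter_mm)
  expect_equal(s2$mean_relative_density_change_pct,
               s$mean_relative_density_change_pct)
  expect_error(summarize_timepoint(m[1, ], target = c("L1", "L2")),
               "missing at timepoint: L2")
  expect_error(summarize_timepoint(rbind(m, m[1, ])), "multiple rows per lesion")
})
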
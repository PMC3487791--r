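test_that("geometric primitives: relative change, sphere and ellipsoid volumes", {
  expect_equal(relative_change(100, 70), -30)
  expect_equal(relative_change(50, 50), 0)
  expect_equal(relative_change(10, 12), 20)
  expect_error(relative_change(0, 10), "positive")

  expect_equal(sphere_volume(2), pi * 8 / 6)
  expect_equal(sphere_volume(0.7) / sphere_volume(1), 0.343)
  expect_equal(sphere_volume(4), 8 * sphere_volume(2))
  expect_error(sphere_volume(-1), "positive")

  expect_equal(ellipsoid_volume(1, 1, 1), sphere_volume(2))
  expect_equal(ellipsoid_volume(1, 1, 2), 8 * pi / 3)
  # shrinking only the longest axis by 30% shrinks volume by exactly 30%
  expect_equal(ellipsoid_volume(1, 1, 0.7 * 2) / ellipsoid_volume(1, 1, 2), 0.7)
  expect_error(ellipsoid_volume(1, 0, 1), "positive")
})

test_that("sphere cut-offs derive by the cube law and invert", {
  sph <- derive_sphere_cutoffs(recist_cutoffs())
  expect_equal(sph$pr_cutoff_pct, 100 * (0.7^3 - 1))   # -65.7
  expect_equal(sph$pd_cutoff_pct, 100 * (1.2^3 - 1))   # +72.8
  expect_equal(derive_sphere_cutoffs(cutoff_set("RECIST", 0, 0))[2:3],
               list(pr_cutoff_pct = 0, pd_cutoff_pct = 0))
  d50 <- derive_sphere_cutoffs(cutoff_set("RECIST", -50, 50))
  expect_equal(d50$pr_cutoff_pct, -87.5)
  expect_equal(d50$pd_cutoff_pct, 237.5)
  # cube-root inverse recovers (-30, +20) to 1e-9
  inv <- function(p) 100 * ((1 + p / 100)^(1 / 3) - 1)
  expect_equal(inv(sph$pr_cutoff_pct), -30, tolerance = 1e-9)
  expect_equal(inv(sph$pd_cutoff_pct), 20, tolerance = 1e-9)
  expect_error(cutoff_set("X", 10, 20), "<=")
})

test_that("cut-off sets round-trip through JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  write_cutoffs(sphere_cutoffs(), path)
  back <- read_cutoffs(path)
  expect_equal(back, sphere_cutoffs())
})

test_that("classify_recist applies -30/+20 boundaries and the new-lesion override", {
  s0 <- make_summary(timepoint_months = 0, sum_d = 100, total_v = 20)
  pr <- classify_recist(make_summary(sum_d = 70), s0)
  expect_equal(pr$category, "PR")
  expect_equal(pr$size_change_pct, -30)
  expect_equal(classify_recist(make_summary(sum_d = 119), s0)$category, "SD")
  expect_equal(classify_recist(make_summary(sum_d = 120), s0)$category, "PD")
  expect_equal(classify_recist(make_summary(sum_d = 90), s0,
                               new_lesion = TRUE)$category, "PD")
  # new lesion overrides even a size-based PR
  expect_equal(classify_recist(make_summary(sum_d = 50), s0,
                               new_lesion = TRUE)$category, "PD")
  s0_other <- make_summary(timepoint_months = 0, sum_d = 100, total_v = 20,
                           lesion_ids = c("L9"))
  expect_error(classify_recist(make_summary(sum_d = 70), s0_other),
               "mismatched target sets")
})

test_that("classify_volume separates sphere and ellipsoid cut-offs", {
  s0 <- make_summary(timepoint_months = 0, sum_d = 100, total_v = 20)
  expect_equal(classify_volume(make_summary(total_v = 6.8), s0,
                               sphere_cutoffs())$category, "PR")  # -66%
  s30 <- make_summary(total_v = 14)                               # -30%
  expect_equal(classify_volume(s30, s0, ellipsoid_cutoffs())$category, "PR")
  expect_equal(classify_volume(s30, s0, sphere_cutoffs())$category, "SD")
  same <- make_summary(total_v = 20)
  expect_equal(classify_volume(same, s0, sphere_cutoffs())$category, "SD")
  expect_equal(classify_volume(same, s0, ellipsoid_cutoffs())$category, "SD")
})

test_that("classify_choi combines size and density rules", {
  s0 <- make_summary(timepoint_months = 0, sum_d = 100, total_v = 20)
  st <- function(sd, dc) make_summary(sum_d = sd, density_change = dc)
  expect_equal(classify_choi(st(88, -5), s0)$category, "PR")    # size -12%
  expect_equal(classify_choi(st(104, -20), s0)$category, "PR")  # density -20%
  expect_equal(classify_choi(st(111, -2), s0)$category, "PD")   # size +11%
  expect_equal(classify_choi(st(104, -2), s0)$category, "SD")
  expect_equal(classify_choi(st(88, -5), s0, new_nodule = TRUE)$category, "PD")
  # density missing: size-only call, flagged
  call <- classify_choi(st(95, NA), s0)
  expect_equal(call$category, "SD")
  expect_true(call$density_missing)
  expect_equal(classify_choi(st(89, NA), s0)$category, "PR")
})

test_that("classify_size_change is boundary-inclusive in both directions", {
  expect_equal(classify_size_change(100, 80)$direction, "DECREASE")
  expect_equal(classify_size_change(100, 81)$direction, "NO_CHANGE")
  expect_equal(classify_size_change(100, 119)$direction, "NO_CHANGE")
  expect_equal(classify_size_change(10, 12)$direction, "INCREASE")
  expect_equal(classify_size_change(100, 50, threshold_pct = 60)$direction,
               "NO_CHANGE")
})

test_that("category moves only PR -> SD -> PD as size change increases", {
  s0 <- make_summary(timepoint_months = 0, sum_d = 100, total_v = 100)
  ord <- c(PR = 1, SD = 2, PD = 3)
  for (cuts in list(recist_cutoffs(), sphere_cutoffs(), ellipsoid_cutoffs())) {
    changes <- seq(-90, 150, by = 2.5)
    cats <- vapply(changes, function(ch) {
      st <- make_summary(sum_d = 100 * (1 + ch / 100),
                         total_v = 100 * (1 + ch / 100))
      if (cuts$criteria == "RECIST") classify_recist(st, s0)$category
      else classify_volume(st, s0, cuts)$category
    }, character(1))
    expect_true(all(diff(ord[cats]) >= 0), info = cuts$criteria)
  }
})

test_that("sphere criteria match RECIST on isotropic cube-law histories", {
  set.seed(401)
  sph <- sphere_cutoffs()
  for (i in 1:300) {
    s0 <- make_summary(timepoint_months = 0, sum_d = runif(1, 20, 150),
                       total_v = runif(1, 1, 300))
    rho <- runif(1, 0.3, 2.2)
    nl <- runif(1) < 0.15
    st <- make_summary(sum_d = s0$sum_longest_diameter_mm * rho,
                       total_v = s0$total_volume_mL * rho^3)
    expect_identical(classify_recist(st, s0, nl)$category,
                     classify_volume(st, s0, sph, nl)$category)
  }
})

test_that("ellipsoid criteria match RECIST when only the longest axis changes", {
  set.seed(402)
  ell <- ellipsoid_cutoffs()
  for (i in 1:300) {
    r12 <- runif(2, 5, 15)
    r3 <- runif(1, 16, 40)
    rho <- runif(1, 0.4, 2)
    s0 <- make_summary(timepoint_months = 0, sum_d = 2 * r3,
                       total_v = ellipsoid_volume(r12[1], r12[2], r3) / 1000)
    st <- make_summary(sum_d = 2 * r3 * rho,
                       total_v = ellipsoid_volume(r12[1], r12[2],
                                                  r3 * rho) / 1000)
    expect_identical(classify_recist(st, s0)$category,
                     classify_volume(st, s0, ell)$category)
  }
})
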
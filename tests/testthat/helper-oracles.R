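# Independent oracles and fixture builders shared across tests.

# Exhaustive symmetry-test oracle in exact integer arithmetic: enumerates the
# full joint configuration space over off-diagonal pairs and sums the
# configurations whose binomial-coefficient product does not exceed the
# observed one (coefficients and their products stay below 2^53 for the pair
# totals used in tests, so doubles are exact and no tolerance is needed).
oracle_symmetry_p <- function(tab) {
  ij <- which(upper.tri(tab), arr.ind = TRUE)
  a <- tab[ij]
  b <- t(tab)[ij]
  n <- a + b
  keep <- n > 0
  a <- a[keep]
  n <- n[keep]
  if (!length(n)) return(1)
  obs <- prod(choose(n, a))
  grid <- expand.grid(lapply(n, function(np) 0:np))
  coef <- rep(1, nrow(grid))
  for (j in seq_along(n)) coef <- coef * choose(n[j], grid[[j]])
  sum(coef[coef <= obs]) / 2^sum(n)
}

# random square table with bounded discordant pair totals
random_square_table <- function(k = 3, max_pair_total = 12) {
  m <- matrix(0L, k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    n <- sample(0:max_pair_total, 1)
    x <- if (n > 0) stats::rbinom(1, n, stats::runif(1, 0.15, 0.85)) else 0L
    m[i, j] <- as.integer(x)
    m[j, i] <- as.integer(n - x)
  }
  diag(m) <- sample(0:6, k, replace = TRUE)
  m
}

# 1-row measurement record with sensible defaults
make_measurement <- function(patient_id = "P1", lesion_id = "L1",
                             timepoint_months = 0L, method = "manual",
                             reader_id = "R1", longest_diameter_mm = 30,
                             volume_mL = 14.1, mean_density_HU = NA_real_,
                             r1_mm = NA_real_, r2_mm = NA_real_,
                             r3_mm = NA_real_, new_lesion = FALSE,
                             new_nodule = FALSE) {
  data.frame(patient_id = patient_id, lesion_id = lesion_id,
             timepoint_months = as.integer(timepoint_months),
             method = method, reader_id = reader_id,
             longest_diameter_mm = longest_diameter_mm,
             volume_mL = volume_mL, mean_density_HU = mean_density_HU,
             r1_mm = r1_mm, r2_mm = r2_mm, r3_mm = r3_mm,
             new_lesion = new_lesion, new_nodule = new_nodule,
             stringsAsFactors = FALSE)
}

# baseline/follow-up summary pair for classifier tests (no file round trip)
make_summary <- function(patient_id = "P1", timepoint_months = 3L,
                         sum_d = 100, total_v = 20,
                         density_change = NA_real_, n_lesions = 1L,
                         lesion_ids = paste0("L", seq_len(n_lesions))) {
  out <- data.frame(patient_id = patient_id,
                    timepoint_months = as.integer(timepoint_months),
                    method = "manual", n_lesions = n_lesions,
                    sum_longest_diameter_mm = sum_d,
                    total_volume_mL = total_v,
                    mean_density_HU = NA_real_,
                    mean_relative_density_change_pct = density_change,
                    stringsAsFactors = FALSE)
  attr(out, "lesion_ids") <- lesion_ids
  out
}

# expand a cross-classification matrix into two named call vectors
calls_from_table <- function(tab) {
  labels <- rownames(tab)
  a <- character(0); b <- character(0)
  for (i in seq_along(labels)) for (j in seq_along(labels)) {
    cnt <- tab[i, j]
    a <- c(a, rep(labels[i], cnt))
    b <- c(b, rep(labels[j], cnt))
  }
  ids <- sprintf("P%03d", seq_along(a))
  names(a) <- names(b) <- ids
  list(a = a, b = b)
}

# small config used by several tests: quick to simulate, default noise
quick_config <- function(...) {
  simulation_config(n_patients = 40, seed = 11, ...)
}

zero_noise_config <- function(...) {
  simulation_config(reader_variability_1d_pct = 0,
                    reader_variability_3d_pct = 0,
                    method_variability_1d_pct = 0,
                    method_variability_3d_pct = 0,
                    density_noise_sd_HU = 0, ...)
}
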
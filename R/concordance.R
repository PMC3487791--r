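# Concordance statistics: paired cross-tabulation, the exact conditional test
# of table symmetry used for sparse paired classifications, Bland-Altman
# limits of agreement and Spearman rank correlation.

.as_call_vector <- function(x, arg = "calls") {
  if (is.data.frame(x)) {
    if (!all(c("patient_id", "category") %in% names(x)))
      stop(arg, " data frame needs patient_id and category columns")
    out <- as.character(x$category)
    names(out) <- as.character(x$patient_id)
    return(out)
  }
  if (is.null(names(x)) || any(names(x) == ""))
    stop(arg, " must be a named vector (names = patient ids) or a data frame")
  out <- as.character(x)
  names(out) <- names(x)
  out
}

#' Cross-tabulate two paired classifications
#'
#' Builds the k x k table whose `[i, j]` cell counts patients classified in
#' category `i` by the first classifier and `j` by the second. Both inputs
#' must cover exactly the same patients.
#'
#' @param calls_a,calls_b named character vectors (names are patient ids) or
#'   data frames with `patient_id` and `category`.
#' @param labels ordered category labels shared by both classifiers.
#' @return integer matrix with `labels` as both dimnames.
#' @export
cross_tabulate <- function(calls_a, calls_b, labels) {
  a <- .as_call_vector(calls_a, "calls_a")
  b <- .as_call_vector(calls_b, "calls_b")
  only_a <- setdiff(names(a), names(b))
  only_b <- setdiff(names(b), names(a))
  if (length(only_a) || length(only_b))
    stop("patients present in one series only: ",
         paste(c(only_a, only_b), collapse = ", "))
  bad <- unique(c(a, b)[!(c(a, b) %in% labels)])
  if (length(bad))
    stop("categories outside label universe: ", paste(bad, collapse = ", "))
  ids <- names(a)
  tab <- table(factor(a[ids], levels = labels),
               factor(b[ids], levels = labels))
  m <- matrix(as.integer(tab), nrow = length(labels),
              dimnames = list(labels, labels))
  m
}

#' Exact test of table symmetry for paired classifications
#'
#' Tests the null hypothesis that a square paired cross-classification is
#' symmetric (no systematic disagreement between the two classifiers).
#' Conditional on each off-diagonal pair total `n_ij + n_ji` (i < j), the
#' split is Binomial(n, 1/2) under the null and the pairs are independent.
#' The exact two-sided p-value sums the null probabilities of all off-diagonal
#' configurations whose probability does not exceed that of the observed
#' configuration (probability ordering); diagonal cells are ignored and empty
#' pairs contribute nothing. This is the classical exact analogue of Bowker's
#' test (and of McNemar's test for k = 2), recommended for sparse tables.
#'
#' When every non-empty discordant pair total is 25 or more the asymptotic
#' Bowker chi-square statistic `sum (n_ij - n_ji)^2 / (n_ij + n_ji)` is used
#' instead (the enumeration is then both unnecessary and expensive).
#'
#' @param x square integer matrix of counts (k >= 2).
#' @param max_configs enumeration guard: fall back to the asymptotic test if
#'   the configuration space exceeds this many points.
#' @return list of class `symmetry_test` with `p_value`, `n_discordant`,
#'   `method` (`"exact"` or `"asymptotic_bowker"`), `statistic` and `df` (the
#'   latter two for the asymptotic branch).
#' @export
exact_symmetry_test <- function(x, max_configs = 2e7) {
  if (!is.matrix(x) || nrow(x) != ncol(x))
    stop("x must be a square matrix of counts")
  if (nrow(x) < 2) stop("need at least 2 categories")
  if (any(x < 0) || any(x != round(x))) stop("counts must be non-negative integers")
  k <- nrow(x)
  ij <- which(upper.tri(x), arr.ind = TRUE)
  a <- x[ij]                          # n_ij, i < j
  b <- t(x)[ij]                       # n_ji
  n <- a + b
  keep <- n > 0
  a <- a[keep]; n <- n[keep]; b <- b[keep]
  n_discordant <- sum(n)
  if (!length(n)) {
    return(structure(list(p_value = 1, n_discordant = 0L, method = "exact",
                          statistic = NA_real_, df = NA_integer_, table = x),
                     class = "symmetry_test"))
  }
  n_configs <- prod(n + 1)
  use_exact <- any(n < 25) && n_configs <= max_configs
  if (use_exact) {
    # joint log-probability grid over all pair splits; the (1/2)^N factor is
    # common to every configuration so ordering uses coefficients only
    logcoefs <- lapply(n, function(np) lchoose(np, 0:np))
    loggrid <- Reduce(function(u, v) as.vector(outer(u, v, "+")), logcoefs)
    logobs <- sum(lchoose(n, a))
    # "<= observed probability" with 1e-12 relative tolerance (spec'd to keep
    # exactly-tied configurations, which are exact in rational arithmetic)
    qual <- loggrid <= logobs + 1e-12
    p <- sum(exp(loggrid[qual] - n_discordant * log(2)))
    p <- min(p, 1)
    return(structure(list(p_value = p, n_discordant = n_discordant,
                          method = "exact", statistic = NA_real_,
                          df = NA_integer_, table = x),
                     class = "symmetry_test"))
  }
  stat <- sum((a - b)^2 / n)
  df <- length(n)
  structure(list(p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 n_discordant = n_discordant, method = "asymptotic_bowker",
                 statistic = stat, df = df, table = x),
            class = "symmetry_test")
}

#' @export
print.symmetry_test <- function(x, ...) {
  cat(sprintf("Test of table symmetry (%s)\n", x$method))
  cat(sprintf("  discordant pairs n = %d, p = %.5g\n",
              x$n_discordant, x$p_value))
  if (x$method == "asymptotic_bowker")
    cat(sprintf("  chi-square = %.4g, df = %d\n", x$statistic, x$df))
  invisible(x)
}

#' Bland-Altman agreement between two measurement series
#'
#' Computes the bias (mean difference, sign convention `a - b`), 95% limits of
#' agreement `bias +/- 1.96 * sd(a - b)`, the Spearman rank correlation of the
#' pairs, and a relative variability defined as the mean symmetric percent
#' difference `mean(|a - b| / ((a + b)/2)) * 100` (only meaningful for
#' positive measurements).
#'
#' @param a,b numeric vectors of paired measurements (length >= 3).
#' @return list of class `bland_altman`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 3) stop("need at least 3 pairs")
  d <- a - b
  bias <- mean(d)
  sd_d <- stats::sd(d)
  rel_var <- if (all(a > 0) && all(b > 0))
    mean(abs(d) / ((a + b) / 2)) * 100 else NA_real_
  sp <- tryCatch(spearman_cor(a, b),
                 error = function(e) list(estimate = NA_real_,
                                          p_value = NA_real_))
  structure(list(bias = bias,
                 loa_low = bias - 1.96 * sd_d,
                 loa_high = bias + 1.96 * sd_d,
                 sd_diff = sd_d,
                 spearman_r = sp$estimate,
                 spearman_p = sp$p_value,
                 relative_variability_pct = rel_var,
                 n = length(a),
                 sign_convention = "first argument minus second (a - b)"),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement (n = %d, difference = %s)\n",
              x$n, x$sign_convention))
  cat(sprintf("  bias %.4g, 95%% LoA [%.4g, %.4g]\n",
              x$bias, x$loa_low, x$loa_high))
  cat(sprintf("  relative variability %.3g%%, Spearman r = %.3f\n",
              x$relative_variability_pct, x$spearman_r))
  invisible(x)
}

#' Spearman rank correlation with a two-sided p-value
#'
#' Correlation of average ranks; the p-value uses the exact null distribution
#' of the rank statistic for n <= 10 without ties, and the t approximation
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom otherwise.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list of class `spearman_test` with `estimate`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: rank correlation undefined")
  r <- stats::cor(rank(x), rank(y))
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 10 && !ties) {
    p <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value)
    method <- "exact"
  } else {
    if (abs(r) >= 1) {
      p <- 0
    } else {
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    method <- "t-approximation"
  }
  structure(list(estimate = r, p_value = p, n = n, method = method),
            class = "spearman_test")
}

#' @export
print.spearman_test <- function(x, ...) {
  cat(sprintf("Spearman rank correlation: r = %.4f, p = %.4g (n = %d, %s)\n",
              x$estimate, x$p_value, x$n, x$method))
  invisible(x)
}
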
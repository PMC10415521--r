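#' Repeatability coefficient of variation
#'
#' Per-subject CV = (sample SD / mean) x 100 over that subject's repeated
#' measurements; the pooled repeatability CV is the root-mean-square of the
#' per-subject CVs (the standard repeatability pooling, which reduces to
#' the single-subject formula when only one subject is supplied). Subjects
#' with zero mean are excluded with a warning.
#'
#' @param data data frame with one row per repeated measurement.
#' @param value column holding the measurement (tidy-eval).
#' @param subject column identifying the subject (tidy-eval).
#' @return A `cv_result`: `cv_pct` (pooled), `per_subject` tibble,
#'   `n_subjects`.
#' @export
coefficient_of_variation <- function(data, value, subject) {
  value <- enquo(value); subject <- enquo(subject)
  per <- data |>
    dplyr::group_by(!!subject) |>
    dplyr::summarise(mu = mean(!!value), sigma = sd(!!value),
                     n_repeats = dplyr::n(), .groups = "drop")
  if (any(per$n_repeats < 2)) {
    abort("Every subject needs at least 2 repeated measurements.",
          class = "bpemri_degenerate_data_error")
  }
  bad <- per$mu == 0
  if (any(bad)) {
    warn(sprintf("%d subject(s) with zero mean excluded from the CV.",
                 sum(bad)))
    per <- per[!bad, , drop = FALSE]
  }
  if (nrow(per) == 0) {
    abort("No subjects with non-zero mean.",
          class = "bpemri_degenerate_data_error")
  }
  per$cv_pct <- per$sigma / per$mu * 100
  structure(
    list(cv_pct = sqrt(mean(per$cv_pct^2)), per_subject = per,
         n_subjects = nrow(per)),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> pooled CV ", signif(x$cv_pct, 4), "% over ",
      x$n_subjects, " subject(s)\n", sep = "")
  invisible(x)
}

#' @describeIn coefficient_of_variation per-subject CV table.
#' @param x a `cv_result`.
#' @param ... unused.
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) as_tibble(x$per_subject)

#' @describeIn coefficient_of_variation one-row pooled summary.
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble(cv_pct = x$cv_pct, n_subjects = x$n_subjects)
}

#' Bland-Altman agreement between paired measurements
#'
#' Differences are taken right minus left. The bias is the mean difference,
#' the reproducibility coefficient (RPC) is 1.96 times the sample standard
#' deviation of the differences, and the limits of agreement are bias
#' plus/minus RPC.
#'
#' @param data data frame with one row per subject.
#' @param right,left columns holding the paired measurements (tidy-eval).
#' @return A `bland_altman` object: `bias`, `sd_diff`, `rpc`, `loa_low`,
#'   `loa_high`, `n_pairs`, and `points` (mean of pair vs difference, the
#'   plotting export).
#' @export
bland_altman <- function(data, right, left) {
  right <- eval_tidy(enquo(right), data)
  left <- eval_tidy(enquo(left), data)
  keep <- is.finite(right) & is.finite(left)
  right <- right[keep]; left <- left[keep]
  if (length(right) < 2) {
    abort("Need at least 2 complete pairs.",
          class = "bpemri_insufficient_data_error")
  }
  d <- right - left
  bias <- mean(d)
  sd_diff <- sd(d)
  rpc <- 1.96 * sd_diff
  structure(
    list(bias = bias, sd_diff = sd_diff, rpc = rpc,
         loa_low = bias - rpc, loa_high = bias + rpc,
         n_pairs = length(d),
         points = tibble(mean_pair = (right + left) / 2, diff = d)),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat("<bland_altman> n = ", x$n_pairs, ", bias ", signif(x$bias, 4),
      ", RPC +/- ", signif(x$rpc, 4), "\n", sep = "")
  invisible(x)
}

#' @describeIn bland_altman the (mean of pair, difference) points.
#' @param x a `bland_altman` object.
#' @param ... unused.
#' @method tidy bland_altman
#' @export
tidy.bland_altman <- function(x, ...) x$points

#' @describeIn bland_altman one-row summary of bias and limits.
#' @method glance bland_altman
#' @export
glance.bland_altman <- function(x, ...) {
  tibble(bias = x$bias, sd_diff = x$sd_diff, rpc = x$rpc,
         loa_low = x$loa_low, loa_high = x$loa_high, n_pairs = x$n_pairs)
}

# ---- rank tests with exact small-sample enumeration ---------------------

#' Two-sample and paired location tests
#'
#' `mann_whitney_u()` and `wilcoxon_signed_rank()` return exact two-sided
#' p-values by exhaustive enumeration (all group labelings, respectively
#' all sign patterns) whenever the combined sample size is at most
#' `exact_limit`; larger samples use the normal approximation with tie
#' correction and continuity correction. `student_t()` and `paired_t()`
#' wrap the two-sided t tests. All p-values are two-sided.
#'
#' @param a,b numeric samples (equal length for the paired tests).
#' @param exact_limit maximum combined n for exhaustive enumeration.
#' @return One-row tibble: `test`, `statistic`, `p_value`, `n1`, `n2`,
#'   `exact`.
#' @name location_tests
NULL

#' @rdname location_tests
#' @export
mann_whitney_u <- function(a, b, exact_limit = 12L) {
  a <- as.numeric(a); b <- as.numeric(b)
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1 || n2 < 1) abort("Both samples must be non-empty.",
                              class = "bpemri_insufficient_data_error")
  u <- u_statistic(a, b)
  centre <- n1 * n2 / 2
  if (n1 + n2 <= exact_limit) {
    p <- mw_exact_p(a, b, u)
    exact <- TRUE
  } else {
    pooled <- c(a, b)
    n <- n1 + n2
    ties <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (abs(u - centre) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(max(z, 0), lower.tail = FALSE))
    exact <- FALSE
  }
  tibble(test = "mann_whitney_u", statistic = u, p_value = p,
         n1 = n1, n2 = n2, exact = exact)
}

# U = number of (a_i, b_j) pairs with a_i > b_j, ties counting 1/2 —
# equivalently the rank-sum form.
u_statistic <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

# Exact two-sided p: proportion of the C(n1+n2, n1) group labelings whose
# U deviates from the null centre at least as much as observed.
mw_exact_p <- function(a, b, u_obs) {
  pooled <- c(a, b)
  n1 <- length(a)
  centre <- n1 * length(b) / 2
  dev_obs <- abs(u_obs - centre) - 1e-9
  labelings <- combn(length(pooled), n1)
  devs <- apply(labelings, 2, function(ix) {
    abs(u_statistic(pooled[ix], pooled[-ix]) - centre)
  })
  mean(devs >= dev_obs)
}

#' @rdname location_tests
#' @export
wilcoxon_signed_rank <- function(a, b, exact_limit = 12L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) {
    abort("Paired samples must have equal length.",
          class = "bpemri_insufficient_data_error")
  }
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    abort("All paired differences are zero: signed-rank test undefined.",
          class = "bpemri_degenerate_data_error")
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  centre <- n * (n + 1) / 4
  if (n <= exact_limit) {
    dev_obs <- abs(w - centre) - 1e-9
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    devs <- abs(as.numeric(signs %*% r) - centre)
    p <- mean(devs >= dev_obs)
    exact <- TRUE
  } else {
    ties <- table(abs(d))
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (abs(w - centre) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(max(z, 0), lower.tail = FALSE))
    exact <- FALSE
  }
  tibble(test = "wilcoxon_signed_rank", statistic = w, p_value = p,
         n1 = n, n2 = n, exact = exact)
}

#' @rdname location_tests
#' @export
student_t <- function(a, b) {
  ht <- t.test(a, b, var.equal = TRUE)
  tibble(test = "student_t", statistic = unname(ht$statistic),
         p_value = ht$p.value, n1 = length(a), n2 = length(b),
         exact = FALSE)
}

#' @rdname location_tests
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) {
    abort("Paired samples must have equal length.",
          class = "bpemri_insufficient_data_error")
  }
  ht <- t.test(a, b, paired = TRUE)
  tibble(test = "paired_t", statistic = unname(ht$statistic),
         p_value = ht$p.value, n1 = length(a), n2 = length(b),
         exact = FALSE)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (tie-aware). The p-value uses the t
#' approximation on n - 2 degrees of freedom, or a seeded permutation test
#' when `n_perm` is given (recommended for small n).
#'
#' @param x,y equal-length samples (n >= 3).
#' @param n_perm number of permutations for a permutation p-value (0 = t
#'   approximation).
#' @param rng_seed seed for the permutation draw.
#' @return One-row tibble: `r`, `p_value`, `n`, `method`.
#' @export
spearman_r <- function(x, y, n_perm = 0L, rng_seed = 1L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3) {
    abort("Need equal-length samples with n >= 3.",
          class = "bpemri_insufficient_data_error")
  }
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    abort("Zero rank variance: correlation undefined.",
          class = "bpemri_degenerate_data_error")
  }
  r <- stats::cor(rx, ry)
  n <- length(x)
  if (n_perm > 0) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                     envir = globalenv())
    }, add = TRUE)
    set.seed(rng_seed)
    perm <- replicate(n_perm, abs(stats::cor(rx, sample(ry))))
    p <- (sum(perm >= abs(r) - 1e-12) + 1) / (n_perm + 1)
    method <- "permutation"
  } else if (abs(r) >= 1) {
    p <- 0
    method <- "t_approx"
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(abs(tstat), n - 2, lower.tail = FALSE)
    method <- "t_approx"
  }
  tibble(r = r, p_value = p, n = n, method = method)
}

#' Multivariable linear model for BPE kurtosis
#'
#' Ordinary least squares of a kurtosis outcome on age, a binary risk-group
#' indicator, and (optionally) their interaction, with t-based 95%
#' confidence intervals — the model used to ask whether a group difference
#' in BPE kurtosis is attributable to age, risk, or their interaction.
#'
#' @param data data frame with the outcome and covariates.
#' @param kurtosis,age,risk columns (tidy-eval); `risk` is coerced to 0/1.
#' @param with_interaction include the age x risk term.
#' @param conf_level confidence level for the intervals.
#' @return A `kurtosis_regression` object wrapping the `lm` fit; `tidy()`
#'   gives per-coefficient estimates, CIs and p-values.
#' @export
kurtosis_regression <- function(data, kurtosis, age, risk,
                                with_interaction = TRUE,
                                conf_level = 0.95) {
  df <- tibble(
    kurtosis = eval_tidy(enquo(kurtosis), data),
    age = eval_tidy(enquo(age), data),
    risk = as.numeric(as.factor(eval_tidy(enquo(risk), data))) - 1
  )
  df <- df[complete.cases(df), , drop = FALSE]
  form <- if (with_interaction) kurtosis ~ age * risk else
    kurtosis ~ age + risk
  n_coef <- if (with_interaction) 4L else 3L
  if (nrow(df) <= n_coef) {
    abort("More coefficients than observations.",
          class = "bpemri_insufficient_data_error")
  }
  fit <- lm(form, data = df)
  if (any(is.na(coef(fit))) || fit$rank < n_coef) {
    abort("Rank-deficient design (collinear covariates or single group).",
          class = "bpemri_collinearity_error")
  }
  structure(list(fit = fit, conf_level = conf_level, n = nrow(df)),
            class = "kurtosis_regression")
}

#' @export
print.kurtosis_regression <- function(x, ...) {
  cat("<kurtosis_regression> n = ", x$n, "\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' @describeIn kurtosis_regression coefficient table with CIs and p-values.
#' @param x a `kurtosis_regression`.
#' @param ... unused.
#' @method tidy kurtosis_regression
#' @export
tidy.kurtosis_regression <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  ci <- confint(x$fit, level = x$conf_level)
  tibble(term = rownames(sm), estimate = sm[, 1], std_error = sm[, 2],
         statistic = sm[, 3], p_value = sm[, 4],
         conf_low = ci[, 1], conf_high = ci[, 2])
}

#' @describeIn kurtosis_regression one-row model summary.
#' @method glance kurtosis_regression
#' @export
glance.kurtosis_regression <- function(x, ...) {
  sm <- summary(x$fit)
  tibble(r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
         sigma = sm$sigma, n = x$n,
         df_residual = x$fit$df.residual)
}

#' Per-metric group comparison table
#'
#' For each metric, reports the per-group median and quartiles and a
#' two-sided p-value for the group difference. The test is chosen per
#' metric: `"auto"` (default) screens both groups for normality
#' (Shapiro-Wilk at 0.05) and uses Student's t when both pass, otherwise
#' the Mann-Whitney U test; `"t"` or `"mw"` force the choice. Metrics with
#' fewer than 3 values in either group are skipped with a warning.
#'
#' @param data data frame, one row per subject, containing the metric
#'   columns and a group column with exactly two levels.
#' @param metrics character vector of metric column names.
#' @param group column holding the group label (tidy-eval).
#' @param test `"auto"`, `"t"` or `"mw"`; recycled over metrics.
#' @return Tibble with one row per (non-skipped) metric: group summaries,
#'   test used, statistic and p-value.
#' @export
cohort_compare <- function(data, metrics, group, test = "auto") {
  grp <- as.factor(eval_tidy(enquo(group), data))
  lev <- levels(grp)
  if (length(lev) != 2) {
    abort("`group` must have exactly two levels.",
          class = "bpemri_configuration_error")
  }
  test <- rep(test, length.out = length(metrics))
  rows <- purrr::map2(metrics, test, function(metric, tchoice) {
    v <- data[[metric]]
    if (is.null(v)) {
      warn(sprintf("Metric '%s' not found; skipped.", metric))
      return(NULL)
    }
    a <- v[grp == lev[1] & is.finite(v)]
    b <- v[grp == lev[2] & is.finite(v)]
    if (length(a) < 3 || length(b) < 3) {
      warn(sprintf("Metric '%s' skipped: a group has fewer than 3 values.",
                   metric))
      return(NULL)
    }
    if (tchoice == "auto") {
      normal_ok <- tryCatch(
        shapiro.test(a)$p.value > 0.05 && shapiro.test(b)$p.value > 0.05,
        error = function(e) FALSE)
      tchoice <- if (normal_ok) "t" else "mw"
    }
    res <- switch(tchoice,
                  t = student_t(a, b),
                  mw = mann_whitney_u(a, b),
                  abort(sprintf("Unknown test '%s'.", tchoice),
                        class = "bpemri_configuration_error"))
    qa <- quantile(a, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    qb <- quantile(b, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    tibble(metric = metric,
           group1 = lev[1], median1 = qa[2], q1_1 = qa[1], q3_1 = qa[3],
           n1 = length(a),
           group2 = lev[2], median2 = qb[2], q1_2 = qb[1], q3_2 = qb[3],
           n2 = length(b),
           test = res$test, statistic = res$statistic,
           p_value = res$p_value, exact = res$exact)
  })
  dplyr::bind_rows(purrr::compact(rows))
}
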
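test_that("coefficient of variation matches hand computation", {
  d0 <- tibble::tibble(subject = "a", value = c(10, 10))
  expect_equal(coefficient_of_variation(d0, value, subject)$cv_pct, 0)
  d1 <- tibble::tibble(subject = "a", value = c(8, 12))
  # sample SD 2*sqrt(2), mean 10
  expect_equal(coefficient_of_variation(d1, value, subject)$cv_pct,
               100 * 2 * sqrt(2) / 10, tolerance = 1e-12)
  # scale invariance
  d2 <- tibble::tibble(subject = rep(c("a", "b"), each = 3),
                       value = c(4, 5, 6, 10, 11, 12))
  cv1 <- coefficient_of_variation(d2, value, subject)$cv_pct
  d3 <- d2; d3$value <- d3$value * 7.3
  expect_equal(coefficient_of_variation(d3, value, subject)$cv_pct, cv1,
               tolerance = 1e-12)
  # order invariance
  d4 <- d2[sample(nrow(d2)), ]
  expect_equal(coefficient_of_variation(d4, value, subject)$cv_pct, cv1)
  # zero-mean subject excluded with warning
  d5 <- tibble::tibble(subject = rep(c("a", "b"), each = 2),
                       value = c(-1, 1, 5, 6))
  expect_warning(cv5 <- coefficient_of_variation(d5, value, subject),
                 regexp = "zero mean")
  expect_equal(cv5$n_subjects, 1L)
})

test_that("Bland-Altman agrees with the hand-computed example", {
  d <- tibble::tibble(r = c(1, 2, 3), l = c(2, 2, 2))
  ba <- bland_altman(d, r, l)
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, 1)
  expect_equal(ba$rpc, 1.96)
  expect_equal(ba$loa_low, -1.96)
  expect_equal(ba$loa_high, 1.96)
  expect_equal(ba$points$mean_pair, c(1.5, 2, 2.5))
  # identical pairs: bias and rpc collapse to zero
  d2 <- tibble::tibble(r = c(3, 4, 5), l = c(3, 4, 5))
  ba2 <- bland_altman(d2, r, l)
  expect_equal(ba2$bias, 0)
  expect_equal(ba2$rpc, 0)
  # swapping sides negates the bias, preserves the RPC
  d3 <- tibble::tibble(r = rnorm(20, 10), l = rnorm(20, 9))
  ba3 <- bland_altman(d3, r, l)
  ba3s <- bland_altman(d3, l, r)
  expect_equal(ba3s$bias, -ba3$bias)
  expect_equal(ba3s$rpc, ba3$rpc)
  expect_error(bland_altman(tibble::tibble(r = 1, l = 2), r, l),
               class = "bpemri_insufficient_data_error")
})

test_that("exact Mann-Whitney p-values match an independent reference", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1)   # 2 of the 20 labelings as extreme
  expect_true(res$exact)
  # identical samples: full overlap, p = 1
  expect_equal(mann_whitney_u(1:4, 1:4)$p_value, 1)
  # tie-free random instances vs the distribution-function route
  set.seed(11)
  for (rep in 1:20) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    a <- rnorm(n1); b <- rnorm(n2, 0.5)
    ours <- mann_whitney_u(a, b)
    ref <- wilcox.test(a, b, exact = TRUE, correct = FALSE)
    expect_true(ours$exact)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("exact Wilcoxon signed-rank p-values match an independent reference", {
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(5:10, 1)
    a <- rnorm(n); b <- a + rnorm(n, 0.3)
    ours <- wilcoxon_signed_rank(a, b)
    ref <- wilcox.test(a, b, paired = TRUE, exact = TRUE, correct = FALSE)
    expect_true(ours$exact)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
  expect_error(wilcoxon_signed_rank(1:5, 1:5),
               class = "bpemri_degenerate_data_error")
})

test_that("normal approximation tracks the exact rank-test p-values", {
  set.seed(13)
  for (rep in 1:10) {
    a <- rnorm(10); b <- rnorm(10, 0.4)
    exact <- mann_whitney_u(a, b, exact_limit = 20L)$p_value
    approx <- mann_whitney_u(a, b, exact_limit = 12L)$p_value
    expect_lt(abs(exact - approx), 0.02)
    pe <- wilcoxon_signed_rank(a, b, exact_limit = 12L)$p_value
    pa <- wilcoxon_signed_rank(a, b, exact_limit = 5L)$p_value
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("Spearman correlation equals the rank-then-Pearson oracle", {
  expect_equal(spearman_r(1:10, (1:10)^2)$r, 1)
  expect_equal(spearman_r(1:10, -(1:10)^3)$r, -1)
  set.seed(14)
  x <- rnorm(20); y <- 0.5 * x + rnorm(20)
  ours <- spearman_r(x, y)
  expect_equal(ours$r, cor(rank(x), rank(y)), tolerance = 1e-12)
  expect_equal(ours$p_value,
               cor.test(x, y, method = "spearman", exact = FALSE)$p.value,
               tolerance = 1e-9)
  perm <- spearman_r(x, y, n_perm = 2000, rng_seed = 3)
  expect_lt(abs(perm$p_value - ours$p_value), 0.05)
  expect_error(spearman_r(rep(1, 5), 1:5),
               class = "bpemri_degenerate_data_error")
})

test_that("the kurtosis regression matches a normal-equations solve", {
  set.seed(15)
  n <- 40
  age <- runif(n, 40, 50)
  risk <- rep(c(0, 1), each = n / 2)
  kurt <- 2 + 0.1 * age - 1.5 * risk + 0.05 * age * risk + rnorm(n, 0, 0.7)
  d <- tibble::tibble(kurt = kurt, age = age, risk = risk)
  fit <- kurtosis_regression(d, kurt, age, risk)
  td <- tidy(fit)
  X <- cbind(1, age, risk, age * risk)
  beta <- solve(t(X) %*% X, t(X) %*% kurt)
  expect_equal(unname(td$estimate), as.numeric(beta), tolerance = 1e-8)
  expect_true(all(td$conf_low <= td$estimate & td$estimate <= td$conf_high))
  # noiseless data are interpolated exactly
  kurt0 <- 2 + 0.1 * age - 1.5 * risk + 0.05 * age * risk
  fit0 <- kurtosis_regression(tibble::tibble(kurt = kurt0, age = age,
                                             risk = risk), kurt, age, risk)
  expect_equal(unname(suppressWarnings(tidy(fit0))$estimate),
               c(2, 0.1, -1.5, 0.05), tolerance = 1e-8)
  # single-group data make the risk terms collinear
  expect_error(
    kurtosis_regression(d[d$risk == 1, ], kurt, age, risk),
    class = "bpemri_collinearity_error")
})

test_that("95% confidence intervals cover the truth at the nominal rate", {
  set.seed(16)
  n <- 40
  age <- runif(n, 40, 50)
  risk <- rep(c(0, 1), each = n / 2)
  true_age_coef <- 0.2
  covered <- replicate(2000, {
    y <- 1 + true_age_coef * age + 0.5 * risk + rnorm(n)
    fit <- kurtosis_regression(
      tibble::tibble(kurt = y, age = age, risk = risk), kurt, age, risk,
      with_interaction = FALSE)
    ci <- tidy(fit)
    ci$conf_low[2] <= true_age_coef & true_age_coef <= ci$conf_high[2]
  })
  expect_lt(abs(mean(covered) - 0.95), 0.02)
})

test_that("group comparison table has the expected shape and honest nulls", {
  set.seed(17)
  d <- tibble::tibble(
    group = rep(c("high", "pop"), each = 6),
    m1 = c(1:6, 1:6),                   # identical groups
    m2 = rnorm(12)
  )
  out <- cohort_compare(d, c("m1", "m2"), group, test = c("mw", "mw"))
  expect_equal(nrow(out), 2)
  expect_equal(out$p_value[out$metric == "m1"], 1)
  expect_true(all(c("median1", "q1_1", "q3_1", "median2", "test",
                    "p_value") %in% names(out)))
  # skipped metrics drop out of the row count with a warning
  d$m3 <- c(rnorm(2), rep(NA, 10))
  expect_warning(out2 <- cohort_compare(d, c("m1", "m3"), group),
                 regexp = "skipped")
  expect_equal(nrow(out2), 1)
})

test_that("a large injected kurtosis shift is detected with high power", {
  set.seed(18)
  detected <- replicate(200, {
    base <- 4.9 + rnorm(30, 0, 1.5)       # population-risk-like spread
    shifted <- base[1:30] * 0 + 4.9 + 3 + rnorm(30, 0, 1.5)
    mann_whitney_u(shifted, base)$p_value < 0.05
  })
  expect_gte(mean(detected), 0.8)
})

test_that("all tests hold their type-I error under the null", {
  set.seed(19)
  n_rep <- 2000
  rejections <- matrix(FALSE, n_rep, 4)
  for (i in seq_len(n_rep)) {
    a <- rnorm(10); b <- rnorm(10)
    rejections[i, 1] <- student_t(a, b)$p_value < 0.05
    rejections[i, 2] <- paired_t(a, b)$p_value < 0.05
    rejections[i, 3] <- mann_whitney_u(a, b)$p_value < 0.05
    rejections[i, 4] <- wilcoxon_signed_rank(a, b)$p_value < 0.05
  }
  rates <- colMeans(rejections)
  for (r in rates) expect_lt(abs(r - 0.05), 0.02)
})
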
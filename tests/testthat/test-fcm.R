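test_that("two well-separated point masses pin the centroids", {
  x <- c(0, 0, 0, 10, 10, 10)
  fit <- fit_fcm(x, K = 2, m = 2)
  expect_equal(fit$centroids, c(0, 10), tolerance = 1e-6)
  expect_true(all(abs(rowSums(fit$memberships) - 1) < 1e-9))
})

test_that("memberships are row-normalised and the objective never rises", {
  set.seed(42)
  for (rep in 1:5) {
    x <- c(rnorm(60, 10, 1), rnorm(40, 25, 2), rnorm(30, 60, 3))
    fit <- fit_fcm(x, K = 4)
    expect_true(all(abs(rowSums(fit$memberships) - 1) < 1e-9))
    expect_true(all(diff(fit$objective_trace) <= 1e-9))
    expect_true(all(diff(fit$centroids) >= 0))
  }
})

test_that("the fit beats random memberships under a brute-force objective", {
  # independent objective evaluator over 1000 random row-normalised
  # membership matrices with their optimal centroids
  set.seed(7)
  x <- rnorm(20, 5, 3)
  fit <- fit_fcm(x, K = 3)
  j_fit <- tail(fit$objective_trace, 1)
  brute <- function(u) {
    um <- u^2
    ctr <- as.numeric(crossprod(um, x) / colSums(um))
    sum(um * outer(x, ctr, "-")^2)
  }
  j_random <- replicate(1000, {
    u <- matrix(runif(20 * 3), 20, 3)
    brute(u / rowSums(u))
  })
  expect_lt(j_fit, min(j_random))
  # and the exported objective evaluator agrees with the trace
  expect_equal(fcm_objective(x, fit$memberships, fit$centroids, m = 2),
               j_fit, tolerance = 1e-9)
})

test_that("degenerate inputs raise the documented errors", {
  expect_error(fit_fcm(c(1, 2), K = 3), class = "bpemri_degenerate_data_error")
  expect_error(fit_fcm(rep(c(1, 2), 10), K = 3),
               class = "bpemri_degenerate_data_error")
  expect_error(fit_fcm(rnorm(10), K = 1), class = "bpemri_parameter_error")
  expect_error(fit_fcm(rnorm(10), K = 2, m = 1),
               class = "bpemri_parameter_error")
})

test_that("segmentation is invariant under affine intensity rescaling", {
  ph <- phantom_clean()
  masks <- cached_masks("clean", ph)
  seg1 <- segment_fgt(ph$t2w, masks$left)
  rescaled <- volume_grid(2.5 * ph$t2w$values + 40, ph$t2w$spacing,
                          ph$t2w$affine)
  seg2 <- segment_fgt(rescaled, masks$left)
  expect_identical(seg1$fgt_mask$values, seg2$fgt_mask$values)
  expect_equal(seg2$model$centroids, 2.5 * seg1$model$centroids + 40,
               tolerance = 1e-3)
})

test_that("segmentation with a fixed seed is reproducible", {
  ph <- phantom_noisy()
  masks <- cached_masks("noisy", ph)
  a <- segment_fgt(ph$t2w, masks$right, jitter_sd = 0.1, rng_seed = 9)
  b <- segment_fgt(ph$t2w, masks$right, jitter_sd = 0.1, rng_seed = 9)
  expect_identical(a$fgt_mask$values, b$fgt_mask$values)
})

test_that("a crafted two-intensity breast is segmented voxel-exactly", {
  # fat = 200 everywhere, FGT = 80 in a central block; default rule picks
  # the lowest clusters (count clamped to the supportable cluster number)
  dm <- c(20, 20, 20)
  v <- array(200, dm)
  fgt <- array(FALSE, dm)
  fgt[6:12, 6:12, 6:12] <- TRUE
  v[fgt] <- 80
  vg <- volume_grid(v, c(1, 1, 1))
  mask <- breast_mask(array(TRUE, dm), c(1, 1, 1))
  seg <- suppressMessages(segment_fgt(vg, mask))
  expect_identical(seg$fgt_mask$values, fgt)
})

test_that("cluster-selection overrides behave as set algebra", {
  ph <- phantom_clean()
  masks <- cached_masks("clean", ph)
  bias <- correct_bias(ph$t2w, masks$bilateral)
  seg_all <- segment_fgt(bias$corrected, masks$left, selection = 1:7)
  expect_identical(seg_all$fgt_mask$values, masks$left$values)
  expect_error(segment_fgt(bias$corrected, masks$left, selection = integer(0)),
               class = "bpemri_configuration_error")
  expect_error(segment_fgt(bias$corrected, masks$left, selection = c(1, 9)),
               class = "bpemri_configuration_error")
  expect_error(segment_fgt(bias$corrected, masks$left, selection = "oddest:3"),
               class = "bpemri_configuration_error")
})

test_that("maximum-membership ties break toward the lower cluster", {
  # a voxel exactly midway between two centroids has equal memberships
  u <- rbind(c(0.5, 0.5), c(0.2, 0.8))
  expect_identical(bpemri:::hard_assign(u), c(1L, 2L))
})

test_that("density arithmetic follows the definitions", {
  dm <- c(10, 10, 10)
  breast <- array(FALSE, dm); breast[1:10, 1:10, 1:10] <- TRUE
  fgt <- array(FALSE, dm); fgt[1:10, 1:5, 1:5] <- TRUE   # 250 of 1000
  bm <- breast_mask(breast, c(1, 1, 1))
  fm <- breast_mask(fgt, c(1, 1, 1))
  d <- compute_density(fm, bm)
  expect_equal(d$fgt_volume_cc, 0.25)
  expect_equal(d$breast_volume_cc, 1)
  expect_equal(d$mrbd_pct, 25)
  # empty FGT gives zero density; empty breast errors
  d0 <- compute_density(breast_mask(array(FALSE, dm), c(1, 1, 1)), bm)
  expect_equal(d0$mrbd_pct, 0)
  expect_error(compute_density(fm, breast_mask(array(FALSE, dm), c(1, 1, 1))),
               class = "bpemri_empty_mask_error")
})

test_that("noiseless phantom density is recovered through FCM", {
  ph <- phantom_clean()
  masks <- cached_masks("clean", ph)
  bias <- correct_bias(ph$t2w, masks$bilateral)
  segs <- lapply(list(masks$left, masks$right), function(side) {
    seg <- segment_fgt(bias$corrected, side)
    compute_density(seg, side)
  })
  dens <- dplyr::bind_rows(segs)
  mrbd <- 100 * sum(dens$fgt_volume_cc) / sum(dens$breast_volume_cc)
  expect_lt(abs(mrbd - ph$truth$true_mrbd_pct), 2)
})
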
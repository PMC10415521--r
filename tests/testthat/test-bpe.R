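# Small crafted series: 4 x 4 x 2 grid, parenchyma block with controlled
# per-frame intensities.
crafted_series <- function(frame_values, pre = 100) {
  dm <- c(4L, 4L, 2L)
  n_t <- length(frame_values) + 1L
  arr <- array(10, dim = c(dm, n_t))
  par <- array(FALSE, dm)
  par[2:3, 2:3, ] <- TRUE
  arr[, , , 1][par] <- pre
  for (t in seq_along(frame_values)) {
    arr[, , , t + 1L][par] <- frame_values[t]
  }
  list(dce = dce_series(arr, spacing = c(1, 1, 1),
                        times_s = (0:(n_t - 1)) * 59.1),
       mask = breast_mask(par, c(1, 1, 1)))
}

test_that("parenchyma segmentation recovers the phantom FGT on DCE", {
  ph <- phantom_clean()
  masks <- cached_masks("clean", ph)
  for (lat in c("left", "right")) {
    side_dce <- resample_mask(masks[[lat]], ph$dce)
    par <- segment_parenchyma_precontrast(ph$dce, side_dce)
    truth_fgt <- ph$truth$fgt_mask$values &
      ph$truth[[paste0("breast_mask_", lat)]]$values
    expect_gt(dice(par$fgt_mask$values, truth_fgt), 0.95)
  }
})

test_that("exclusion masks are honoured and cannot empty the breast silently", {
  ph <- cached_phantom("fsfail", noise_sigma = 0,
                       fat_sup_failure_fraction = 0.03)
  masks <- cached_masks("fsfail", ph)
  side <- resample_mask(masks$right, ph$dce)
  patch <- ph$truth$fat_sup_failure_mask
  with_excl <- segment_parenchyma_precontrast(ph$dce, side, exclusion = patch)
  expect_equal(sum(with_excl$fgt_mask$values & patch$values), 0)
  # without exclusion the bright failure patch contaminates the parenchyma
  without <- segment_parenchyma_precontrast(ph$dce, side)
  expect_gt(sum(without$fgt_mask$values & patch$values), 0)
  all_mask <- breast_mask(array(TRUE, dim(ph$dce$values)[1:3]),
                          ph$dce$spacing, ph$dce$affine)
  expect_error(
    segment_parenchyma_precontrast(ph$dce, side, exclusion = all_mask),
    class = "bpemri_empty_mask_error")
})

test_that("MTP selection is the argmax of post-contrast parenchymal medians", {
  cs <- crafted_series(c(10, 20, 30, 40, 50, 60))
  expect_identical(select_mtp(cs$dce, cs$mask), 7L)
  # plateau with the maximum median at post-contrast frame 5 of 6
  cs2 <- crafted_series(c(10, 30, 50, 60, 70, 70))
  expect_identical(select_mtp(cs2$dce, cs2$mask), 6L)
  # all-identical post-contrast frames: earliest wins
  cs3 <- crafted_series(rep(40, 6))
  expect_identical(select_mtp(cs3$dce, cs3$mask), 2L)
  # type I phantom peaks at the final frame
  ph <- phantom_clean()
  masks <- cached_masks("clean", ph)
  side <- resample_mask(masks$right, ph$dce)
  par <- segment_parenchyma_precontrast(ph$dce, side)
  expect_identical(select_mtp(ph$dce, par), dim(ph$dce$values)[4])
})

test_that("the enhancement formula is evaluated per voxel", {
  cs <- crafted_series(c(100, 150), pre = 100)
  res <- suppressWarnings(compute_bpe_map(cs$dce, cs$mask, mtp_index = 2L))
  expect_true(all(res$bpe_map_pct == 0))
  res2 <- suppressWarnings(compute_bpe_map(cs$dce, cs$mask, mtp_index = 3L))
  expect_true(all(res2$bpe_map_pct == 50))
  expect_identical(res2$ftp_index, 1L)
  expect_gt(res2$mtp_index, res2$ftp_index)
})

test_that("BPE is scale-invariant and monotone in the MTP frame", {
  ph <- phantom_clean()
  masks <- cached_masks("clean", ph)
  side <- resample_mask(masks$right, ph$dce)
  par <- segment_parenchyma_precontrast(ph$dce, side)
  res <- compute_bpe_map(ph$dce, par)
  scaled <- ph$dce
  scaled$values <- scaled$values * 4.2
  res_scaled <- compute_bpe_map(scaled, par, mtp_index = res$mtp_index)
  expect_equal(res_scaled$bpe_map_pct, res$bpe_map_pct, tolerance = 1e-12)
  # constant positive offset on only the MTP frame raises every voxel
  shifted <- ph$dce
  shifted$values[, , , res$mtp_index] <-
    shifted$values[, , , res$mtp_index] + 5
  res_shift <- compute_bpe_map(shifted, par, mtp_index = res$mtp_index)
  expect_true(all(res_shift$bpe_map_pct > res$bpe_map_pct))
})

test_that("noiseless phantom BPE median matches the generated distribution", {
  ph <- phantom_clean()
  masks <- cached_masks("clean", ph)
  for (lat in c("left", "right")) {
    side <- resample_mask(masks[[lat]], ph$dce)
    par <- segment_parenchyma_precontrast(ph$dce, side)
    res <- compute_bpe_map(ph$dce, par)
    expect_lt(abs(res$summary$median - median(truth_enhancement(ph, lat))), 1)
  }
})

test_that("left and right metrics agree exactly on a noise-free phantom", {
  ph <- phantom_clean()
  res <- run_subject(ph$t2w, ph$dce, subject_id = "sym")
  # geometry is symmetric; enhancement draws differ per breast, so compare
  # each side against its own ground truth instead of against each other
  expect_equal(res$mrbd_pct[1], res$mrbd_pct[2])
  for (i in 1:2) {
    ev <- truth_enhancement(ph, res$laterality[i])
    expect_equal(res$bpe_median_pct[i], median(ev), tolerance = 1e-9)
    expect_equal(res$bpe_kurtosis[i], moment_kurtosis(ev), tolerance = 1e-9)
  }
})

test_that("distribution summary follows the stated conventions", {
  s <- summarise_distribution(1:5)
  expect_equal(s$median, 3)
  expect_equal(s$q1, 2)
  expect_equal(s$q3, 4)
  expect_equal(s$iqr, 2)
  expect_equal(s$skewness, 0, tolerance = 1e-12)
  # any symmetric sample has zero skewness
  sym <- c(-3, -1, -0.5, 0.5, 1, 3)
  expect_lt(abs(summarise_distribution(sym)$skewness), 1e-12)
  # zero variance: quantiles survive, moments are flagged
  expect_warning(dz <- summarise_distribution(rep(2, 10)),
                 regexp = "Zero variance")
  expect_equal(dz$median, 2)
  expect_true(is.na(dz$skewness) && is.na(dz$kurtosis) && dz$degenerate)
  expect_error(summarise_distribution(c(1, 2, 3)),
               class = "bpemri_degenerate_data_error")
})

test_that("Monte-Carlo kurtosis pins the non-excess convention", {
  set.seed(2024)
  expect_equal(summarise_distribution(rnorm(1e6))$kurtosis, 3,
               tolerance = 0.05 / 3)
  expect_equal(summarise_distribution(runif(1e6))$kurtosis, 1.8,
               tolerance = 0.05 / 1.8)
})

test_that("low pre-contrast denominators are dropped and counted", {
  cs <- crafted_series(c(200, 210), pre = 100)
  # put one parenchyma voxel's pre-contrast intensity near zero
  idx <- which(cs$mask$values)[1]
  cs$dce$values[, , , 1][idx] <- 1e-4
  res <- suppressWarnings(compute_bpe_map(cs$dce, cs$mask, mtp_index = 3L))
  expect_identical(res$n_dropped_denominator, 1L)
  expect_equal(length(res$bpe_map_pct), sum(cs$mask$values) - 1)
  # all-dropped is an explicit error
  cs$dce$values[, , , 1][cs$mask$values] <- 0
  expect_error(compute_bpe_map(cs$dce, cs$mask, mtp_index = 3L),
               class = "bpemri_domain_error")
})
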
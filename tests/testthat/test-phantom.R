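test_that("SPGR signal obeys its analytic limits and monotonicity", {
  expect_equal(spgr_signal(0), 0)
  # saturation: very fast relaxation drives the signal to s0 * sin(FA)
  expect_equal(spgr_signal(1e6, tr_ms = 4.24, fa_deg = 12, s0 = 100),
               100 * sin(12 * pi / 180), tolerance = 1e-10)
  r1 <- seq(0.1, 5, length.out = 50)
  expect_true(all(diff(spgr_signal(r1)) > 0))
  expect_true(all(spgr_signal(r1, s0 = 3) <= 3 * sin(12 * pi / 180)))
  expect_error(spgr_signal(1, tr_ms = -1), class = "bpemri_parameter_error")
  expect_error(spgr_signal(1, fa_deg = 95), class = "bpemri_parameter_error")
  # inverse round-trips through the forward model
  s <- spgr_signal(c(0.3, 0.8, 2), s0 = 50)
  expect_equal(spgr_r1_for_signal <- bpemri:::spgr_r1_for_signal(s, s0 = 50),
               c(0.3, 0.8, 2), tolerance = 1e-10)
})

test_that("kinetic templates start at zero and peak where they should", {
  expect_equal(kinetic_curve("type1_persistent", 0, 6), 0)
  expect_equal(kinetic_curve("type1_persistent", 6, 6), 1)
  f <- kinetic_curve("type1_persistent", 0:6, 6)
  expect_true(all(diff(f) > 0))
  p <- kinetic_curve("plateau", 0:6, 6)
  expect_equal(p[1], 0)
  expect_true(all(diff(p) >= 0))
  expect_equal(max(p), 1)
  expect_error(kinetic_curve("washout", 1, 6),
               class = "bpemri_parameter_error")
  expect_error(kinetic_curve("plateau", 7, 6),
               class = "bpemri_parameter_error")
})

test_that("phantom config invariants are enforced", {
  expect_error(phantom_config(fgt_fraction = 0), class = "bpemri_parameter_error")
  expect_error(phantom_config(fgt_fraction = 1.2), class = "bpemri_parameter_error")
  expect_error(phantom_config(noise_sigma = -0.1), class = "bpemri_parameter_error")
  expect_error(phantom_config(n_post = 0), class = "bpemri_parameter_error")
  expect_error(phantom_config(dt_s = 0), class = "bpemri_parameter_error")
})

test_that("ground-truth density equals the voxel-count ratio exactly", {
  for (f in c(0.07, 0.2, 0.35)) {
    ph <- generate_phantom(phantom_config(grid_shape = c(48, 72, 24),
                                          fgt_fraction = f, rng_seed = 5))
    breast <- truth_breast_values(ph)
    fgt <- ph$truth$fgt_mask$values
    expect_true(all(fgt[!breast] == FALSE))   # FGT inside the breast
    expect_equal(ph$truth$true_mrbd_pct, 100 * sum(fgt & breast) / sum(breast))
    # achieved fraction within voxel quantisation of the target
    expect_lt(abs(ph$truth$true_mrbd_pct - 100 * f),
              100 / sum(ph$truth$breast_mask_left$values))
  }
})

test_that("identical config and seed give bit-identical phantoms", {
  a <- generate_phantom(phantom_config(grid_shape = c(32, 48, 16),
                                       rng_seed = 17))
  b <- generate_phantom(phantom_config(grid_shape = c(32, 48, 16),
                                       rng_seed = 17))
  expect_identical(a$t2w$values, b$t2w$values)
  expect_identical(a$dce$values, b$dce$values)
  expect_identical(a$truth$true_voxel_enhancement_pct,
                   b$truth$true_voxel_enhancement_pct)
  c <- generate_phantom(phantom_config(grid_shape = c(32, 48, 16),
                                       rng_seed = 18))
  expect_false(identical(a$t2w$values, c$t2w$values))
})

test_that("emitted frames reproduce the drawn voxel enhancements", {
  # oracle: recompute (I_last - I_first) / I_first x 100 from raw frames
  ph <- generate_phantom(phantom_config(noise_sigma = 0, bias_amplitude = 0,
                                        enhancement_median_pct = 30))
  fgt <- ph$truth$fgt_mask$values
  n_t <- dim(ph$dce$values)[4]
  i_first <- ph$dce$values[, , , 1][fgt]
  i_last <- ph$dce$values[, , , n_t][fgt]
  recomputed <- 100 * (i_last - i_first) / i_first
  expect_equal(recomputed, ph$truth$true_voxel_enhancement_pct[fgt],
               tolerance = 1e-9)
  expect_lt(abs(median(recomputed) - 30), 1)
})

test_that("T2w contrast places FGT below fat and suppresses fat on DCE", {
  ph <- phantom_flat()
  fgt <- ph$truth$fgt_mask$values
  fat <- truth_breast_values(ph) & !fgt
  expect_lt(max(ph$t2w$values[fgt]), min(ph$t2w$values[fat]))
  pre <- ph$dce$values[, , , 1]
  expect_lt(max(pre[fat]), min(pre[fgt]) / 5)
})

test_that("phantom writes round-trip through NIfTI", {
  ph <- generate_phantom(phantom_config(grid_shape = c(24, 40, 16),
                                        rng_seed = 2))
  d <- withr::local_tempdir()
  write_phantom(ph, d)
  t2 <- read_volume(file.path(d, "t2w.nii.gz"))
  expect_equal(t2$values, ph$t2w$values, tolerance = 1e-12)
  truth <- jsonlite::read_json(file.path(d, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$true_mrbd_pct, ph$truth$true_mrbd_pct)
  m <- read_mask(file.path(d, "truth_fgt.nii.gz"))
  expect_identical(m$values, ph$truth$fgt_mask$values)
})
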
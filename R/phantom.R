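#' Steady-state spoiled gradient-echo signal
#'
#' The standard SPGR steady-state equation
#' \deqn{S = s_0 \sin\alpha \, (1 - E_1) / (1 - \cos\alpha \, E_1), \quad
#'       E_1 = \exp(-TR \cdot R_1)}
#' used by the phantom to map longitudinal relaxation rate to signal. The
#' signal is bounded above by \eqn{s_0 \sin\alpha} (the sequence's dynamic
#' range) and strictly increasing in `r1_per_s`, which is what limits how
#' much enhancement a DCE protocol can register.
#'
#' @param tr_ms repetition time (ms), > 0. Default 4.24 ms.
#' @param fa_deg flip angle (degrees), in (0, 90). Default 12.
#' @param r1_per_s longitudinal relaxation rate R1 = 1/T1 (1/s); vectorised.
#' @param s0 equilibrium signal scale (arbitrary units).
#' @return Signal in arbitrary units, same length as `r1_per_s`.
#' @export
spgr_signal <- function(r1_per_s, tr_ms = 4.24, fa_deg = 12, s0 = 1) {
  if (length(tr_ms) != 1 || !is.finite(tr_ms) || tr_ms <= 0) {
    abort("`tr_ms` must be a single positive number.",
          class = "bpemri_parameter_error")
  }
  if (length(fa_deg) != 1 || !is.finite(fa_deg) || fa_deg <= 0 ||
      fa_deg >= 90) {
    abort("`fa_deg` must lie strictly between 0 and 90 degrees.",
          class = "bpemri_parameter_error")
  }
  if (any(r1_per_s < 0)) {
    abort("`r1_per_s` must be non-negative.", class = "bpemri_parameter_error")
  }
  a <- fa_deg * pi / 180
  e1 <- exp(-tr_ms / 1000 * r1_per_s)
  s0 * sin(a) * (1 - e1) / (1 - cos(a) * e1)
}

# Invert the SPGR equation: the R1 that produces signal `s` (0 <= s <
# s0*sin(fa)). Used to realise a prescribed enhancement through the signal
# model.
spgr_r1_for_signal <- function(s, tr_ms = 4.24, fa_deg = 12, s0 = 1) {
  a <- fa_deg * pi / 180
  amp <- s0 * sin(a)
  if (any(s < 0) || any(s >= amp)) {
    abort("Requested signal outside the sequence's dynamic range.",
          class = "bpemri_parameter_error")
  }
  e1 <- (amp - s) / (amp - s * cos(a))
  -log(e1) / (tr_ms / 1000)
}

#' Fractional enhancement reached at a dynamic frame
#'
#' Kinetic template for parenchymal enhancement: fraction of the voxel's
#' peak enhancement present at post-contrast frame `t_index` (0 =
#' pre-contrast). `"type1_persistent"` rises monotonically through the
#' series and peaks at the final frame, the pattern normal parenchyma shows;
#' `"plateau"` rises and then holds from 60% of the series onward.
#'
#' @param shape `"type1_persistent"` or `"plateau"`.
#' @param t_index frame index, 0 (pre-contrast) to `n_post`; vectorised.
#' @param n_post number of post-contrast frames (>= 1).
#' @param peak_fraction multiplier applied to the template (unitless).
#' @return Fraction of peak enhancement in `[0, peak_fraction]`.
#' @export
kinetic_curve <- function(shape, t_index, n_post, peak_fraction = 1) {
  if (n_post < 1) abort("`n_post` must be >= 1.",
                        class = "bpemri_parameter_error")
  if (any(t_index < 0) || any(t_index > n_post)) {
    abort("`t_index` must lie in 0..n_post.", class = "bpemri_parameter_error")
  }
  f <- switch(
    shape,
    type1_persistent = (1 - exp(-3 * t_index / n_post)) / (1 - exp(-3)),
    plateau = pmin(t_index / max(1, ceiling(0.6 * n_post)), 1),
    abort(sprintf("Unknown kinetic shape '%s'.", shape),
          class = "bpemri_parameter_error")
  )
  f * peak_fraction
}

#' Phantom generation parameters
#'
#' Defaults are the study conditions the phantom emulates: a 64 x 96 x 32
#' grid at 2 mm isotropic (seconds-scale analysis while preserving 3D
#' morphology), seven dynamic frames at 59.1 s spacing with the DCE
#' sequence's TR 4.24 ms / flip angle 12 deg, type I (persistent)
#' parenchymal kinetics, and a right-skewed voxelwise enhancement
#' distribution.
#'
#' @param grid_shape voxel counts per axis; axis 1 is anterior-posterior,
#'   axis 2 left-right, axis 3 superior-inferior.
#' @param voxel_size_mm spacing per axis (mm).
#' @param fgt_fraction target fibro-glandular volume fraction in (0, 1).
#' @param bias_amplitude peak fractional deviation of the multiplicative
#'   bias field (0 disables it).
#' @param noise_sigma additive Gaussian noise SD as a fraction of the mean
#'   breast-tissue signal.
#' @param enhancement_median_pct target median % enhancement of parenchyma
#'   at the final frame.
#' @param enhancement_spread_pct target inter-quartile range of the
#'   voxelwise % enhancement.
#' @param kinetic_shape `"type1_persistent"` or `"plateau"`.
#' @param n_post number of post-contrast frames.
#' @param dt_s frame interval (s).
#' @param fat_sup_failure_fraction fraction of breast voxels in which fat
#'   suppression fails on the dynamic frames.
#' @param rng_seed integer seed; identical config + seed gives bit-identical
#'   phantoms.
#' @param tr_ms,fa_deg,s0 SPGR parameters of the dynamic sequence.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(grid_shape = c(64L, 96L, 32L),
                           voxel_size_mm = c(2, 2, 2),
                           fgt_fraction = 0.20,
                           bias_amplitude = 0.15,
                           noise_sigma = 0.02,
                           enhancement_median_pct = 30,
                           enhancement_spread_pct = 15,
                           kinetic_shape = "type1_persistent",
                           n_post = 6L,
                           dt_s = 59.1,
                           fat_sup_failure_fraction = 0,
                           rng_seed = 1L,
                           tr_ms = 4.24, fa_deg = 12, s0 = 4000) {
  cfg <- list(grid_shape = as.integer(grid_shape),
              voxel_size_mm = as.numeric(voxel_size_mm),
              fgt_fraction = fgt_fraction,
              bias_amplitude = bias_amplitude,
              noise_sigma = noise_sigma,
              enhancement_median_pct = enhancement_median_pct,
              enhancement_spread_pct = enhancement_spread_pct,
              kinetic_shape = kinetic_shape,
              n_post = as.integer(n_post),
              dt_s = dt_s,
              fat_sup_failure_fraction = fat_sup_failure_fraction,
              rng_seed = as.integer(rng_seed),
              tr_ms = tr_ms, fa_deg = fa_deg, s0 = s0)
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  if (length(cfg$grid_shape) != 3L || any(cfg$grid_shape < 16L)) {
    abort("`grid_shape` must give three axes of at least 16 voxels.",
          class = "bpemri_parameter_error")
  }
  if (cfg$fgt_fraction <= 0 || cfg$fgt_fraction >= 1) {
    abort("`fgt_fraction` must lie in (0, 1).",
          class = "bpemri_parameter_error")
  }
  if (cfg$noise_sigma < 0) abort("`noise_sigma` must be >= 0.",
                                 class = "bpemri_parameter_error")
  if (cfg$n_post < 1L) abort("`n_post` must be >= 1.",
                             class = "bpemri_parameter_error")
  if (cfg$dt_s <= 0) abort("`dt_s` must be > 0.",
                           class = "bpemri_parameter_error")
  if (cfg$bias_amplitude < 0 || cfg$bias_amplitude >= 1) {
    abort("`bias_amplitude` must lie in [0, 1).",
          class = "bpemri_parameter_error")
  }
  if (cfg$fat_sup_failure_fraction < 0 || cfg$fat_sup_failure_fraction > 0.5) {
    abort("`fat_sup_failure_fraction` must lie in [0, 0.5].",
          class = "bpemri_parameter_error")
  }
  invisible(cfg)
}

# Tissue intensity design (arbitrary units). The T2w contrast places FGT
# below fat; each tissue carries a few well-separated sub-modes so that a
# seven-cluster intensity model resolves three FGT and four fat clusters.
.t2w_fgt_modes <- c(150, 190, 230)
.t2w_fat_modes <- c(300, 340, 380, 420)
.t2w_skin <- 340
.t2w_muscle <- 15
.t2w_air <- 5
.dce_fgt_r1 <- c(0.55, 0.70, 0.85)   # 1/s, pre-contrast parenchymal R1 modes
.dce_fat_suppressed <- c(5, 9)       # residual fat signal after suppression
.dce_fat_failure <- 180              # unenhancing bright fat where FS fails
.dce_muscle <- 25
.dce_skin <- 12
.dce_air <- 2

#' Generate a synthetic paired T2w + DCE breast dataset with ground truth
#'
#' Builds bilateral hemi-ellipsoidal breasts on a chest-wall slab with a
#' 2-voxel skin rind, places a connected lobulated fibro-glandular region
#' achieving `fgt_fraction` of the breast volume, renders a non-fat-
#' suppressed T2w volume (FGT darker than fat) and a fat-suppressed dynamic
#' series whose parenchymal signals follow the configured kinetics through
#' the SPGR signal model, then applies a smooth multiplicative bias field
#' and additive Gaussian noise. Every generative quantity is returned as
#' ground truth for parameter-recovery testing.
#'
#' @param cfg a [phantom_config()].
#' @return A list with elements `t2w` ([volume_grid()]), `dce`
#'   ([dce_series()]), `truth` (ground-truth masks, bias field, enhancement
#'   map and scalars) and `config`.
#' @export
generate_phantom <- function(cfg = phantom_config()) {
  validate_phantom_config(cfg)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(cfg$rng_seed)

  dm <- cfg$grid_shape
  sp <- cfg$voxel_size_mm
  affine <- phantom_affine(dm, sp)

  # voxel index arrays
  ii <- slice.index(array(0, dm), 1)
  jj <- slice.index(array(0, dm), 2)
  kk <- slice.index(array(0, dm), 3)

  # geometry in voxel units, scaled to the default 64 x 96 x 32 layout
  sc <- dm / c(64, 96, 32)
  i0 <- 6.5 * sc[1]                      # breast base depth
  a_i <- 40 * sc[1]; b_j <- 20 * sc[2]; c_k <- 14 * sc[3]
  k_c <- (dm[3] + 1) / 2
  j_right <- (dm[2] + 1) / 2 + 22 * sc[2]
  j_left  <- (dm[2] + 1) / 2 - 22 * sc[2]

  rho_r <- sqrt(((ii - i0) / a_i)^2 + ((jj - j_right) / b_j)^2 +
                  ((kk - k_c) / c_k)^2)
  rho_l <- sqrt(((ii - i0) / a_i)^2 + ((jj - j_left) / b_j)^2 +
                  ((kk - k_c) / c_k)^2)
  bulge_r <- ii > i0 & rho_r <= 1
  bulge_l <- ii > i0 & rho_l <= 1
  muscle <- ii <= i0
  full <- bulge_r | bulge_l

  # breast proper = bulge minus the 2-voxel rind (skin + chest-wall
  # interface); the rind is the skin label
  core <- morph_erode(full, 2L)
  skin <- full & !core
  core_r <- core & bulge_r
  core_l <- core & bulge_l
  if (!any(core_r) || !any(core_l)) {
    abort("Grid too small: breast interior vanished after the skin rind.",
          class = "bpemri_geometry_error")
  }

  # lobulated FGT field: ellipsoidal coordinate around the breast centre
  # plus a smooth mirror-symmetric modulation; threshold at the voxel-count
  # quantile achieving fgt_fraction per breast
  fgt <- array(FALSE, dm)
  n_sub <- array(NA_integer_, dm)       # FGT sub-mode label 1..3
  for (side in c("r", "l")) {
    jc <- if (side == "r") j_right else j_left
    rho_core <- if (side == "r") rho_r else rho_l
    core_s <- if (side == "r") core_r else core_l
    ic_f <- i0 + 0.3 * a_i
    rf <- sqrt(((ii - ic_f) / (0.75 * a_i))^2 + ((jj - jc) / (0.75 * b_j))^2 +
                 ((kk - k_c) / (0.75 * c_k))^2)
    lob <- rf + 0.18 * cos(1.1 * (ii - ic_f) / sc[1]) *
      cos(0.9 * (jj - jc) / sc[2]) * cos(0.7 * (kk - k_c) / sc[3])
    vals <- lob[core_s]
    n_take <- round(cfg$fgt_fraction * length(vals))
    if (n_take < 1) {
      abort("`fgt_fraction` unachievable: fewer than one voxel.",
            class = "bpemri_geometry_error")
    }
    thr <- sort(vals, partial = n_take)[n_take]
    sel <- core_s & lob <= thr
    # ties at the threshold: trim to the exact count, deepest first
    if (sum(sel) > n_take) {
      idx <- which(sel)
      keep <- idx[order(lob[idx])][seq_len(n_take)]
      sel[] <- FALSE
      sel[keep] <- TRUE
    }
    fgt <- fgt | sel
    # sub-modes: 6 mm heterogeneity patches, mirror-symmetric between
    # breasts. High-frequency by design so intra-tissue texture stays
    # orthogonal to any smooth (low-order polynomial) intensity model.
    blocks <- (floor(ii / 3) + floor(abs(jj - jc) / 3) + floor(kk / 3))
    n_sub[sel] <- 1L + blocks[sel] %% 3L
  }

  n_breast <- sum(core)
  n_fgt <- sum(fgt)
  true_mrbd_pct <- 100 * n_fgt / n_breast
  true_fgt_volume_cc <- n_fgt * prod(sp) / 1000

  # fat sub-modes: the same 6 mm heterogeneity patches, four levels
  fat <- core & !fgt
  fat_shell <- array(NA_integer_, dm)
  if (any(fat)) {
    jdist <- pmin(abs(jj - j_right), abs(jj - j_left))
    blocks <- (floor(ii / 3) + floor(jdist / 3) + floor(kk / 3))
    fat_shell[fat] <- 1L + blocks[fat] %% 4L
  }

  # ---- T2w volume -----------------------------------------------------
  t2w <- array(.t2w_air, dm)
  t2w[muscle] <- .t2w_muscle
  t2w[skin] <- .t2w_skin
  t2w[fat] <- .t2w_fat_modes[fat_shell[fat]]
  t2w[fgt] <- .t2w_fgt_modes[n_sub[fgt]]

  # ---- bias field ------------------------------------------------------
  bias <- phantom_bias_field(dm, cfg$bias_amplitude)

  # ---- fat-suppression failure patch ----------------------------------
  fs_fail <- array(FALSE, dm)
  if (cfg$fat_sup_failure_fraction > 0 && any(fat)) {
    n_want <- round(cfg$fat_sup_failure_fraction * n_breast)
    # contiguous patch: fat voxels nearest a peripheral anchor in the right
    # breast
    anchor <- c(i0 + 0.55 * a_i, j_right + 0.55 * b_j, k_c)
    d2 <- (ii - anchor[1])^2 + (jj - anchor[2])^2 + (kk - anchor[3])^2
    idx_fat <- which(fat)
    ord <- order(d2[idx_fat])
    fs_fail[idx_fat[ord[seq_len(min(n_want, length(idx_fat)))]]] <- TRUE
  }

  # ---- DCE series ------------------------------------------------------
  s_pre_modes <- spgr_signal(.dce_fgt_r1, cfg$tr_ms, cfg$fa_deg, cfg$s0)
  pre <- array(.dce_air, dm)
  pre[muscle] <- .dce_muscle
  pre[skin] <- .dce_skin
  pre[fat] <- .dce_fat_suppressed[1 + fat_shell[fat] %% 2L]
  pre[fs_fail] <- .dce_fat_failure
  pre[fgt] <- s_pre_modes[n_sub[fgt]]

  # per-voxel peak enhancement: log-normal hitting the target median and
  # IQR, capped just inside the sequence's dynamic range
  idx_fgt <- which(fgt)
  mu_log <- log(cfg$enhancement_median_pct)
  sigma_log <- asinh(cfg$enhancement_spread_pct /
                       (2 * cfg$enhancement_median_pct)) / qnorm(0.75)
  enh_pct <- rlnorm(length(idx_fgt), mu_log, sigma_log)
  amp <- cfg$s0 * sin(cfg$fa_deg * pi / 180)
  s_pre_fgt <- pre[idx_fgt]
  e_max <- 100 * (0.98 * amp / s_pre_fgt - 1)
  n_capped <- sum(enh_pct > e_max)
  enh_pct <- pmin(enh_pct, e_max)

  r1_pre <- .dce_fgt_r1[n_sub[idx_fgt]]
  r1_peak <- spgr_r1_for_signal(s_pre_fgt * (1 + enh_pct / 100),
                                cfg$tr_ms, cfg$fa_deg, cfg$s0)

  n_frames <- cfg$n_post + 1L
  frames <- array(rep(pre, n_frames), dim = c(dm, n_frames))
  fk <- kinetic_curve(cfg$kinetic_shape, 0:cfg$n_post, cfg$n_post)
  for (t in seq_len(cfg$n_post)) {
    r1_t <- r1_pre + (r1_peak - r1_pre) * fk[t + 1]
    fr <- pre
    fr[idx_fgt] <- spgr_signal(r1_t, cfg$tr_ms, cfg$fa_deg, cfg$s0)
    frames[, , , t + 1L] <- fr
  }

  true_enh <- array(NA_real_, dm)
  true_enh[idx_fgt] <- enh_pct

  # ---- bias + noise last ----------------------------------------------
  t2w_ref <- mean(t2w[core])            # mean tissue signal, pre-bias
  dce_ref <- mean(pre[idx_fgt])
  t2w <- t2w * bias
  for (t in seq_len(n_frames)) frames[, , , t] <- frames[, , , t] * bias
  if (cfg$noise_sigma > 0) {
    t2w <- t2w + rnorm(length(t2w), 0, cfg$noise_sigma * t2w_ref)
    frames <- frames + rnorm(length(frames), 0, cfg$noise_sigma * dce_ref)
  }

  times_s <- (0:cfg$n_post) * cfg$dt_s
  truth <- list(
    breast_mask_left = breast_mask(core_l, sp, affine, "left"),
    breast_mask_right = breast_mask(core_r, sp, affine, "right"),
    full_breast_mask = breast_mask(full, sp, affine, "bilateral"),
    skin_mask = breast_mask(skin, sp, affine, "bilateral"),
    fgt_mask = breast_mask(fgt, sp, affine, "bilateral"),
    fat_sup_failure_mask = breast_mask(fs_fail, sp, affine, "bilateral"),
    true_bias_field = volume_grid(bias, sp, affine),
    true_voxel_enhancement_pct = true_enh,
    true_fgt_volume_cc = true_fgt_volume_cc,
    true_mrbd_pct = true_mrbd_pct,
    n_capped_enhancement = n_capped
  )
  list(t2w = volume_grid(t2w, sp, affine),
       dce = dce_series(frames, spacing = sp, affine = affine,
                        times_s = times_s),
       truth = truth, config = cfg)
}

# Affine sending array axis 2 to world x (patient right = +x), axis 1 to
# world y, axis 3 to world z, grid centred at the origin. Putting
# left-right on the second array axis guarantees laterality logic reads the
# affine rather than assuming axis order.
phantom_affine <- function(dm, sp) {
  a <- matrix(0, 4, 4)
  a[1, 2] <- sp[2]; a[2, 1] <- sp[1]; a[3, 3] <- sp[3]; a[4, 4] <- 1
  a[1, 4] <- -sp[2] * (dm[2] - 1) / 2
  a[2, 4] <- -sp[1] * (dm[1] - 1) / 2
  a[3, 4] <- -sp[3] * (dm[3] - 1) / 2
  a
}

# Smooth multiplicative field 1 + amplitude * P(x), P a fixed order-2
# polynomial in centred normalised coordinates with max |P| = 1 over the
# grid. Analytically known, so correction accuracy is directly testable.
phantom_bias_field <- function(dm, amplitude) {
  if (amplitude == 0) return(array(1, dm))
  u <- (slice.index(array(0, dm), 1) - 1) / (dm[1] - 1) * 2 - 1
  v <- (slice.index(array(0, dm), 2) - 1) / (dm[2] - 1) * 2 - 1
  w <- (slice.index(array(0, dm), 3) - 1) / (dm[3] - 1) * 2 - 1
  p <- 0.7 * u + 0.4 * v - 0.3 * w + 0.5 * u * v - 0.35 * v * w +
    0.45 * u^2 - 0.25 * w^2
  p <- p / max(abs(p))
  1 + amplitude * p
}

#' Write a phantom to disk (NIfTI + JSON sidecar)
#'
#' @param phantom result of [generate_phantom()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly. Writes `t2w.nii.gz`, `dce.nii.gz` (+ times
#'   sidecar), uint8 truth masks, the true bias field, and
#'   `truth.json` with the generative config and scalar ground truth.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(phantom$t2w, file.path(dir, "t2w.nii.gz"))
  write_dce(phantom$dce, file.path(dir, "dce.nii.gz"))
  tr <- phantom$truth
  write_volume(tr$breast_mask_left, file.path(dir, "truth_breast_left.nii.gz"))
  write_volume(tr$breast_mask_right,
               file.path(dir, "truth_breast_right.nii.gz"))
  write_volume(tr$fgt_mask, file.path(dir, "truth_fgt.nii.gz"))
  write_volume(tr$skin_mask, file.path(dir, "truth_skin.nii.gz"))
  write_volume(tr$fat_sup_failure_mask,
               file.path(dir, "truth_fs_failure.nii.gz"))
  write_volume(tr$true_bias_field, file.path(dir, "truth_bias.nii.gz"))
  jsonlite::write_json(
    list(config = unclass(phantom$config),
         true_mrbd_pct = tr$true_mrbd_pct,
         true_fgt_volume_cc = tr$true_fgt_volume_cc,
         n_capped_enhancement = tr$n_capped_enhancement),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
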
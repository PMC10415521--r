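#' Segment parenchyma on the pre-contrast dynamic frame
#'
#' Fuzzy c-means (K clusters) on the pre-contrast, fat-suppressed frame
#' within the whole-breast mask (resampled to the DCE geometry), minus any
#' operator-drawn exclusion regions (e.g. fat-suppression failure). On
#' fat-suppressed pre-contrast images parenchyma is bright, so the default
#' selects every cluster above the largest inter-centroid gap
#' (`"gap:high"`); pass `"highest:k"` or an explicit cluster set to
#' fine-tune.
#'
#' @param dce a [dce_series()].
#' @param breast_on_dce [breast_mask()] already on the DCE grid (use
#'   [resample_mask()]).
#' @param exclusion optional [breast_mask()] of regions to drop.
#' @param K,m,selection,tol,max_iter,jitter_sd,rng_seed as in
#'   [segment_fgt()].
#' @return A `tissue_segmentation` of the parenchyma.
#' @export
segment_parenchyma_precontrast <- function(dce, breast_on_dce,
                                           exclusion = NULL, K = 7L, m = 2,
                                           selection = "gap:high",
                                           tol = 1e-6, max_iter = 300L,
                                           jitter_sd = 0, rng_seed = 1L) {
  stopifnot(inherits(dce, "dce_series"), inherits(breast_on_dce, "breast_mask"))
  pre <- dce_frame(dce, dce$pre_contrast_index)
  mask <- breast_on_dce
  if (!is.null(exclusion)) {
    stopifnot(inherits(exclusion, "breast_mask"))
    if (!same_geometry(mask, exclusion)) {
      abort("Exclusion mask must share the DCE geometry.",
            class = "bpemri_format_error")
    }
    mask <- breast_mask(mask$values & !exclusion$values, mask$spacing,
                        mask$affine, mask$laterality,
                        mask$erosion_radius_vox)
  }
  if (!any(mask$values)) {
    abort("No breast voxels remain after exclusion.",
          class = "bpemri_empty_mask_error")
  }
  segment_fgt(pre, mask, K = K, m = m, selection = selection, tol = tol,
              max_iter = max_iter, jitter_sd = jitter_sd, rng_seed = rng_seed)
}

#' Select the maximum-enhancement time point (MTP)
#'
#' The dynamic frame (among post-contrast frames only) with the highest
#' median intensity over the segmented parenchyma; ties go to the earliest
#' such frame. Under type I (persistent) kinetics this is the last or
#' second-to-last frame.
#'
#' @param dce a [dce_series()].
#' @param parenchyma a `tissue_segmentation` (or [breast_mask()]) on the
#'   DCE grid.
#' @return Integer frame index into the series (2 .. n frames).
#' @export
select_mtp <- function(dce, parenchyma) {
  stopifnot(inherits(dce, "dce_series"))
  pmask <- parenchyma_values(parenchyma)
  n_t <- dim(dce$values)[4]
  if (n_t < 2) abort("Series has no post-contrast frames.",
                     class = "bpemri_parameter_error")
  idx <- which(pmask)
  if (length(idx) == 0) abort("Parenchyma mask is empty.",
                              class = "bpemri_empty_mask_error")
  meds <- vapply(2:n_t, function(t) {
    fr <- dce$values[, , , t, drop = TRUE]
    median(fr[idx])
  }, numeric(1))
  as.integer(which.max(meds) + 1L)   # which.max takes the earliest maximum
}

#' Voxelwise background parenchymal enhancement map and summary
#'
#' BPE (%) = 100 x (I_MTP - I_FTP) / I_FTP per parenchyma voxel, where FTP
#' is the pre-contrast frame and MTP the maximum-enhancement frame.
#' Parenchyma voxels whose pre-contrast intensity falls below
#' `denominator_floor_frac` times the parenchymal pre-contrast median are
#' dropped from the map (the ratio is unstable there) and counted in
#' `n_dropped_denominator`. Distribution metrics use linear-interpolation
#' quantiles (type 7), moment skewness g1 = m3 / m2^1.5, and non-excess
#' kurtosis b2 = m4 / m2^2 (normal = 3).
#'
#' @param dce a [dce_series()].
#' @param parenchyma a `tissue_segmentation` (or [breast_mask()]).
#' @param mtp_index frame index of the MTP; `NULL` selects it with
#'   [select_mtp()].
#' @param denominator_floor_frac fraction of the parenchymal pre-contrast
#'   median below which the denominator is considered unusable.
#' @return A `bpe_result`: `bpe_map_pct` (values at `voxel_idx`),
#'   `voxel_idx` (linear indices into the DCE grid), `mtp_index`,
#'   `ftp_index`, `n_dropped_denominator`, `laterality`, grid geometry, and
#'   `summary` (one-row tibble from [summarise_distribution()]).
#' @export
compute_bpe_map <- function(dce, parenchyma, mtp_index = NULL,
                            denominator_floor_frac = 0.01) {
  stopifnot(inherits(dce, "dce_series"))
  pmask <- parenchyma_values(parenchyma)
  idx <- which(pmask)
  if (length(idx) == 0) abort("Parenchyma mask is empty.",
                              class = "bpemri_empty_mask_error")
  if (is.null(mtp_index)) mtp_index <- select_mtp(dce, parenchyma)
  n_t <- dim(dce$values)[4]
  if (mtp_index <= dce$pre_contrast_index || mtp_index > n_t) {
    abort("`mtp_index` must point at a post-contrast frame.",
          class = "bpemri_parameter_error")
  }
  ftp <- dce$values[, , , dce$pre_contrast_index, drop = TRUE][idx]
  mtp <- dce$values[, , , mtp_index, drop = TRUE][idx]
  floor_val <- denominator_floor_frac * median(ftp)
  usable <- ftp > floor_val & ftp > 0
  if (!any(usable)) {
    abort("All parenchyma voxels fell below the denominator floor.",
          class = "bpemri_domain_error")
  }
  bpe <- 100 * (mtp[usable] - ftp[usable]) / ftp[usable]
  lat <- if (inherits(parenchyma, "tissue_segmentation")) {
    parenchyma$laterality
  } else {
    parenchyma$laterality %||% "bilateral"
  }
  structure(
    list(bpe_map_pct = bpe, voxel_idx = idx[usable],
         mtp_index = as.integer(mtp_index),
         ftp_index = dce$pre_contrast_index,
         n_dropped_denominator = sum(!usable),
         laterality = lat, dim = dim(dce$values)[1:3],
         spacing = dce$spacing, affine = dce$affine,
         summary = summarise_distribution(bpe)),
    class = "bpe_result"
  )
}

#' @export
print.bpe_result <- function(x, ...) {
  s <- x$summary
  cat("<bpe_result> ", x$laterality, ", n = ", s$n, " voxels, MTP frame ",
      x$mtp_index, "\n  median ", signif(s$median, 4), "%, IQR ",
      signif(s$iqr, 4), "%, skewness ", signif(s$skewness, 3),
      ", kurtosis ", signif(s$kurtosis, 3), "\n", sep = "")
  invisible(x)
}

#' @describeIn compute_bpe_map one row per parenchyma voxel (linear index
#'   and % enhancement).
#' @param x a `bpe_result`.
#' @param ... unused.
#' @method tidy bpe_result
#' @export
tidy.bpe_result <- function(x, ...) {
  tibble(voxel_idx = x$voxel_idx, bpe_pct = x$bpe_map_pct)
}

#' @describeIn compute_bpe_map one-row distribution summary with MTP/FTP
#'   bookkeeping.
#' @method glance bpe_result
#' @export
glance.bpe_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble(laterality = x$laterality, mtp_index = x$mtp_index,
           ftp_index = x$ftp_index,
           n_dropped_denominator = x$n_dropped_denominator),
    x$summary
  )
}

#' Export a BPE map as a volume (NA outside parenchyma)
#' @param x a `bpe_result`.
#' @return A [volume_grid()]-shaped list whose `values` contain NA outside
#'   the mapped voxels (NIfTI-writable via [write_volume()] after NA
#'   replacement, or used directly for display).
#' @export
bpe_map_volume <- function(x) {
  stopifnot(inherits(x, "bpe_result"))
  vals <- array(NA_real_, x$dim)
  vals[x$voxel_idx] <- x$bpe_map_pct
  structure(list(values = vals, spacing = x$spacing, affine = x$affine),
            class = "volume_grid")
}

#' Summarise a distribution of % enhancements
#'
#' Quantiles use the linear-interpolation convention (R type 7). Skewness
#' is the moment coefficient g1 = m3 / m2^1.5 and kurtosis the non-excess
#' b2 = m4 / m2^2 (normal distribution = 3). With zero variance the
#' quantiles are still returned and the moment metrics are NA with
#' `degenerate = TRUE`.
#'
#' @param values numeric sample (n >= 4 for quartiles).
#' @return One-row tibble: `median`, `q1`, `q3`, `iqr`, `skewness`,
#'   `kurtosis`, `n`, `degenerate`.
#' @export
summarise_distribution <- function(values) {
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  if (length(v) < 4) {
    abort("Need at least 4 values for quartile summaries.",
          class = "bpemri_degenerate_data_error")
  }
  qs <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  m2 <- mean((v - mean(v))^2)
  if (m2 <= 0) {
    warn("Zero variance: skewness and kurtosis are undefined.")
    sk <- ku <- NA_real_
    degenerate <- TRUE
  } else {
    sk <- mean((v - mean(v))^3) / m2^1.5
    ku <- mean((v - mean(v))^4) / m2^2
    degenerate <- FALSE
  }
  tibble(median = qs[2], q1 = qs[1], q3 = qs[3], iqr = qs[3] - qs[1],
         skewness = sk, kurtosis = ku, n = length(v),
         degenerate = degenerate)
}

parenchyma_values <- function(parenchyma) {
  if (inherits(parenchyma, "tissue_segmentation")) {
    parenchyma$fgt_mask$values
  } else if (inherits(parenchyma, "breast_mask")) {
    parenchyma$values
  } else {
    abort("`parenchyma` must be a tissue_segmentation or breast_mask.",
          class = "bpemri_format_error")
  }
}
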
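# Ball structuring-element offsets (voxel units, isotropic radius).
ball_offsets <- function(radius) {
  r <- as.integer(radius)
  g <- expand.grid(di = -r:r, dj = -r:r, dk = -r:r)
  g[g$di^2 + g$dj^2 + g$dk^2 <= radius^2, , drop = FALSE]
}

# Shift a logical array by (di, dj, dk), padding with FALSE.
shift_logical <- function(a, d) {
  dm <- dim(a)
  out <- array(FALSE, dm)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    s <- d[ax]
    if (abs(s) >= dm[ax]) return(out)
    if (s >= 0) {
      dst[[ax]] <- (1 + s):dm[ax]; src[[ax]] <- 1:(dm[ax] - s)
    } else {
      dst[[ax]] <- 1:(dm[ax] + s); src[[ax]] <- (1 - s):dm[ax]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <-
    a[src[[1]], src[[2]], src[[3]]]
  out
}

# Morphological erosion of a logical array with a ball of `radius` voxels.
# Voxels outside the grid count as background.
morph_erode <- function(a, radius) {
  if (radius == 0) return(a)
  out <- a
  offs <- ball_offsets(radius)
  for (r in seq_len(nrow(offs))) {
    d <- as.integer(offs[r, ])
    if (all(d == 0L)) next
    out <- out & shift_logical(a, -d)
    if (!any(out)) break
  }
  out
}

#' Seeded 3D region growing
#'
#' Grows the 26-connected set reachable from the seeds through voxels whose
#' intensity differs from the running region mean by at most `tolerance`.
#' Boundary voxels are admitted best-first (most similar to the running
#' mean first) and the mean is updated as the region grows, which lets the
#' criterion track slow intensity drifts (e.g. a bias field) better than a
#' fixed seed-intensity criterion would.
#'
#' @param volume a [volume_grid()].
#' @param seeds integer matrix of voxel coordinates (rows = seeds, columns
#'   i, j, k; 1-based) or a list of length-3 vectors.
#' @param tolerance admissible absolute intensity deviation from the
#'   running region mean (intensity units, >= 0).
#' @return A bilateral, pre-erosion [breast_mask()] containing all seeds.
#' @export
region_grow <- function(volume, seeds, tolerance) {
  stopifnot(inherits(volume, "volume_grid"))
  if (tolerance < 0) abort("`tolerance` must be >= 0.",
                           class = "bpemri_parameter_error")
  if (is.list(seeds)) seeds <- do.call(rbind, seeds)
  seeds <- matrix(as.integer(seeds), ncol = 3)
  dm <- dim(volume$values)
  if (any(seeds < 1L) || any(seeds[, 1] > dm[1]) || any(seeds[, 2] > dm[2]) ||
      any(seeds[, 3] > dm[3])) {
    abort("Seed coordinates outside the grid.",
          class = "bpemri_coordinate_error")
  }
  v <- volume$values
  lin_seed <- unique(seeds[, 1] + dm[1] * (seeds[, 2] - 1) +
                       dm[1] * dm[2] * (seeds[, 3] - 1))
  acc <- array(FALSE, dm)
  acc[lin_seed] <- TRUE
  sum_int <- sum(v[lin_seed])
  n_acc <- length(lin_seed)

  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]   # 26-connectivity
  lin_offs <- offs[, 1] + dm[1] * offs[, 2] + dm[1] * dm[2] * offs[, 3]

  neighbours_of <- function(lin) {
    fi <- (lin - 1) %% dm[1] + 1
    fj <- ((lin - 1) %/% dm[1]) %% dm[2] + 1
    fk <- (lin - 1) %/% (dm[1] * dm[2]) + 1
    nb <- integer(0)
    for (r in seq_along(lin_offs)) {
      ok <- fi + offs[r, 1] >= 1 & fi + offs[r, 1] <= dm[1] &
        fj + offs[r, 2] >= 1 & fj + offs[r, 2] <= dm[2] &
        fk + offs[r, 3] >= 1 & fk + offs[r, 3] <= dm[3]
      if (any(ok)) nb <- c(nb, lin[ok] + lin_offs[r])
    }
    unique(nb)
  }

  # Best-first admission: each wave admits the boundary candidates closest
  # to the running region mean (within a narrow band above the current
  # best deviation), never beyond `tolerance`. Rejected candidates stay on
  # the boundary and are reconsidered as the mean drifts. Best-first keeps
  # the mean trajectory smooth — the region absorbs its most similar
  # tissue first — so a locally dark sub-region cannot transiently drag
  # the admission band down onto the background.
  band <- tolerance / 24
  cand <- neighbours_of(lin_seed)
  cand <- cand[!acc[cand]]
  while (length(cand) > 0) {
    dev <- abs(v[cand] - sum_int / n_acc)
    best <- min(dev)
    if (best > tolerance) break
    keep <- dev <= min(best + band, tolerance)
    add <- cand[keep]
    acc[add] <- TRUE
    sum_int <- sum_int + sum(v[add])
    n_acc <- n_acc + length(add)
    new_nb <- neighbours_of(add)
    cand <- unique(c(cand[!keep], new_nb))
    cand <- cand[!acc[cand]]
  }
  if (n_acc == length(lin_seed) && length(v) > n_acc) {
    inform("Region growing admitted no voxels beyond the seeds.")
  }
  breast_mask(acc, volume$spacing, volume$affine, laterality = "bilateral")
}

#' Erode a mask with a ball structuring element
#'
#' Removes `radius_vox` voxels from every surface of the mask — the step
#' that strips the skin rind and the chest-wall interface from a grown
#' whole-breast mask.
#'
#' @param mask a [breast_mask()].
#' @param radius_vox ball radius in voxels (>= 0; 0 is the identity).
#' @return The eroded [breast_mask()].
#' @export
erode_mask <- function(mask, radius_vox = 2L) {
  stopifnot(inherits(mask, "breast_mask"))
  if (radius_vox < 0) abort("`radius_vox` must be >= 0.",
                            class = "bpemri_parameter_error")
  out <- morph_erode(mask$values, as.integer(radius_vox))
  if (!any(out)) {
    abort(sprintf(
      "Erosion with radius %d removed the whole mask; reduce the radius.",
      radius_vox), class = "bpemri_empty_mask_error")
  }
  breast_mask(out, mask$spacing, mask$affine, laterality = mask$laterality,
              erosion_radius_vox = mask$erosion_radius_vox +
                as.integer(radius_vox))
}

#' Split a bilateral mask at the mid-sagittal plane
#'
#' Partitions the mask at the grid's mid-sagittal world plane; laterality is
#' decided from world coordinates through the affine (world +x = patient
#' right), never from array order.
#'
#' @param mask a bilateral [breast_mask()].
#' @return A list with elements `left` and `right` ([breast_mask()]s);
#'   together they partition the input. An empty side is flagged with a
#'   warning.
#' @export
split_laterality <- function(mask) {
  stopifnot(inherits(mask, "breast_mask"))
  vg <- list(values = mask$values, affine = mask$affine)
  wx <- world_x_array(vg)
  mid <- mid_sagittal_x(vg)
  right_v <- mask$values & (wx > mid)
  left_v <- mask$values & (wx <= mid)
  if (!any(right_v)) warn("Right side of the mask is empty.")
  if (!any(left_v)) warn("Left side of the mask is empty.")
  list(
    left = breast_mask(left_v, mask$spacing, mask$affine, "left",
                       mask$erosion_radius_vox),
    right = breast_mask(right_v, mask$spacing, mask$affine, "right",
                        mask$erosion_radius_vox)
  )
}

#' Automatic breast seed proposal
#'
#' Fallback for the semi-automated workflow: one seed per image half, the
#' above-threshold voxel nearest the centroid of the bright (adipose)
#' tissue in that half. The threshold is a fraction of the half's maximum
#' intensity.
#'
#' @param volume a [volume_grid()] (non-fat-suppressed T2w).
#' @param threshold_frac fraction of the per-half maximum defining "bright".
#' @return 2 x 3 integer matrix of voxel seeds (right half, left half).
#' @export
auto_seeds <- function(volume, threshold_frac = 0.55) {
  stopifnot(inherits(volume, "volume_grid"))
  wx <- world_x_array(volume)
  mid <- mid_sagittal_x(volume)
  v <- volume$values
  dm <- dim(v)
  seed_for <- function(half) {
    idx <- which(half & v >= threshold_frac * max(v[half]))
    ai <- (idx - 1) %% dm[1] + 1
    aj <- ((idx - 1) %/% dm[1]) %% dm[2] + 1
    ak <- (idx - 1) %/% (dm[1] * dm[2]) + 1
    ctr <- c(mean(ai), mean(aj), mean(ak))
    best <- which.min((ai - ctr[1])^2 + (aj - ctr[2])^2 + (ak - ctr[3])^2)
    c(ai[best], aj[best], ak[best])
  }
  rbind(seed_for(wx > mid), seed_for(wx <= mid))
}

#' Whole-breast masking: grow, erode, split
#'
#' Convenience wrapper for the full masking stage: seeded region growing on
#' the non-fat-suppressed T2w volume, ball erosion to remove the skin and
#' chest wall, then a mid-sagittal laterality split.
#'
#' @param t2w a [volume_grid()].
#' @param seeds voxel seeds as in [region_grow()]; `NULL` uses
#'   [auto_seeds()].
#' @param tolerance region-growing tolerance (intensity units).
#' @param erode_radius_vox erosion ball radius (voxels).
#' @return List with `bilateral`, `left`, `right` masks (post-erosion).
#' @export
mask_breast <- function(t2w, seeds = NULL, tolerance = 240,
                        erode_radius_vox = 2L) {
  if (is.null(seeds)) seeds <- auto_seeds(t2w)
  grown <- region_grow(t2w, seeds, tolerance)
  eroded <- erode_mask(grown, erode_radius_vox)
  sides <- split_laterality(eroded)
  list(bilateral = eroded, left = sides$left, right = sides$right)
}
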
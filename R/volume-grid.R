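#' 3D scalar volume with grid geometry
#'
#' A `volume_grid` couples a 3D numeric array with its voxel spacing and a
#' voxel-to-world affine, the unit every pipeline stage consumes and
#' produces. The package pins one anatomical convention — world +x points
#' towards the patient's right side — and always derives laterality from the
#' affine, never from array order, so display conventions cannot leak into
#' the analysis.
#'
#' @param values numeric 3D array; all values must be finite.
#' @param spacing numeric length-3, voxel edge lengths in mm (all > 0).
#' @param affine 4x4 voxel-to-world matrix mapping 0-based voxel indices
#'   `(i-1, j-1, k-1, 1)` to world mm. Default: axis-aligned, grid centred
#'   on the world origin.
#' @return A `volume_grid` object.
#' @export
volume_grid <- function(values, spacing = c(1, 1, 1), affine = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    abort("`values` must be a 3D array.", class = "bpemri_format_error")
  }
  if (!all(is.finite(values))) {
    abort("`values` must be finite everywhere.", class = "bpemri_format_error")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    abort("`spacing` must be three positive voxel sizes (mm).",
          class = "bpemri_format_error")
  }
  if (is.null(affine)) affine <- default_affine(dim(values), spacing)
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4L, 4L)))
  structure(
    list(values = values, spacing = spacing, affine = affine),
    class = "volume_grid"
  )
}

# Axis-aligned affine with the grid centre at the world origin.
default_affine <- function(dm, spacing) {
  a <- diag(4)
  a[1, 1] <- spacing[1]
  a[2, 2] <- spacing[2]
  a[3, 3] <- spacing[3]
  a[1:3, 4] <- -spacing * (dm - 1) / 2
  a
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> ", paste(dim(x$values), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$values)

#' Voxel volume in cubic centimetres
#' @param v a `volume_grid` or numeric spacing vector (mm).
#' @return voxel volume in cc.
#' @export
voxel_volume_cc <- function(v) {
  sp <- if (inherits(v, "volume_grid")) v$spacing else as.numeric(v)
  prod(sp) / 1000
}

#' World coordinate of one grid axis position
#'
#' World x (the left-right coordinate) for every voxel, as an array matching
#' the grid. Used to split masks at the mid-sagittal plane.
#' @noRd
world_x_array <- function(v) {
  dm <- dim(v$values)
  a <- v$affine
  xi <- a[1, 1] * (seq_len(dm[1]) - 1)
  xj <- a[1, 2] * (seq_len(dm[2]) - 1)
  xk <- a[1, 3] * (seq_len(dm[3]) - 1)
  outer(outer(xi, xj, "+"), xk, "+") + a[1, 4]
}

# Mid-sagittal world-x plane of the *grid* (centre of the world-x extent
# over the 8 grid corners).
mid_sagittal_x <- function(v) {
  dm <- dim(v$values)
  corners <- as.matrix(expand.grid(c(0, dm[1] - 1), c(0, dm[2] - 1),
                                   c(0, dm[3] - 1)))
  xs <- v$affine[1, 1] * corners[, 1] + v$affine[1, 2] * corners[, 2] +
    v$affine[1, 3] * corners[, 3] + v$affine[1, 4]
  mean(range(xs))
}

#' Mirror a volume left-right
#'
#' Reverses the array along the axis that carries the world left-right
#' coordinate while keeping the affine, i.e. a true anatomical reflection
#' about the grid's mid-sagittal plane.
#' @param v a `volume_grid`.
#' @return The reflected `volume_grid`.
#' @export
mirror_lr <- function(v) {
  stopifnot(inherits(v, "volume_grid"))
  ax <- which.max(abs(v$affine[1, 1:3]))
  idx <- lapply(dim(v$values), seq_len)
  idx[[ax]] <- rev(idx[[ax]])
  v$values <- do.call(`[`, c(list(v$values), idx, list(drop = FALSE)))
  v
}

#' Dynamic contrast-enhanced series
#'
#' An ordered stack of co-registered frames (1 pre-contrast + `n_post`
#' post-contrast) sharing one grid geometry. The pre-contrast frame (FTP)
#' is always frame 1.
#'
#' @param frames 4D numeric array (x, y, z, time) or list of `volume_grid`s
#'   sharing one geometry.
#' @param spacing,affine geometry shared by all frames (ignored when
#'   `frames` is a list of `volume_grid`s).
#' @param times_s strictly increasing acquisition time offsets (s), one per
#'   frame.
#' @return A `dce_series` object with elements `values` (4D array),
#'   `spacing`, `affine`, `times_s`, `pre_contrast_index` (always 1).
#' @export
dce_series <- function(frames, spacing = c(1, 1, 1), affine = NULL,
                       times_s = NULL) {
  if (is.list(frames) && all(vapply(frames, inherits, TRUE, "volume_grid"))) {
    aff <- frames[[1]]$affine
    dm <- dim(frames[[1]]$values)
    for (f in frames) {
      if (!identical(dim(f$values), dm) || !isTRUE(all.equal(f$affine, aff))) {
        abort("All frames must share one shape and affine.",
              class = "bpemri_format_error")
      }
    }
    spacing <- frames[[1]]$spacing
    affine <- aff
    frames <- array(unlist(lapply(frames, `[[`, "values")),
                    dim = c(dm, length(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 4L) {
    abort("`frames` must be a 4D array (x, y, z, time).",
          class = "bpemri_format_error")
  }
  n_t <- dim(frames)[4]
  if (is.null(times_s)) times_s <- seq_len(n_t) - 1
  times_s <- as.numeric(times_s)
  if (length(times_s) != n_t || any(diff(times_s) <= 0)) {
    abort("`times_s` must be strictly increasing, one per frame.",
          class = "bpemri_format_error")
  }
  if (is.null(affine)) affine <- default_affine(dim(frames)[1:3], spacing)
  structure(
    list(values = frames, spacing = as.numeric(spacing),
         affine = as.matrix(affine), times_s = times_s,
         pre_contrast_index = 1L),
    class = "dce_series"
  )
}

#' @export
print.dce_series <- function(x, ...) {
  cat("<dce_series> ", paste(dim(x$values)[1:3], collapse = " x "),
      " voxels x ", dim(x$values)[4], " frames (1 pre-contrast)\n", sep = "")
  invisible(x)
}

#' Extract one frame of a DCE series as a `volume_grid`
#' @param dce a `dce_series`.
#' @param index frame index (1 = pre-contrast).
#' @return A `volume_grid`.
#' @export
dce_frame <- function(dce, index) {
  stopifnot(inherits(dce, "dce_series"))
  n_t <- dim(dce$values)[4]
  if (index < 1 || index > n_t) {
    abort(sprintf("Frame index %d outside 1..%d.", index, n_t),
          class = "bpemri_coordinate_error")
  }
  volume_grid(dce$values[, , , index, drop = TRUE], dce$spacing, dce$affine)
}

#' Mirror a DCE series left-right
#' @param dce a `dce_series`.
#' @return The reflected series.
#' @export
mirror_lr_dce <- function(dce) {
  stopifnot(inherits(dce, "dce_series"))
  ax <- which.max(abs(dce$affine[1, 1:3]))
  idx <- lapply(dim(dce$values), seq_len)
  idx[[ax]] <- rev(idx[[ax]])
  dce$values <- do.call(`[`, c(list(dce$values), idx, list(drop = FALSE)))
  dce
}

#' Breast mask on a stated grid geometry
#'
#' @param values logical 3D array.
#' @param spacing,affine grid geometry (as in [volume_grid()]).
#' @param laterality one of `"left"`, `"right"`, `"bilateral"`.
#' @param erosion_radius_vox erosion already applied (voxels), 0 if none.
#' @return A `breast_mask` object.
#' @export
breast_mask <- function(values, spacing = c(1, 1, 1), affine = NULL,
                        laterality = c("bilateral", "left", "right"),
                        erosion_radius_vox = 0L) {
  laterality <- match.arg(laterality)
  if (is.numeric(values)) values <- array(values != 0, dim = dim(values))
  if (!is.array(values) || length(dim(values)) != 3L || !is.logical(values)) {
    abort("`values` must be a logical 3D array.", class = "bpemri_format_error")
  }
  if (is.null(affine)) affine <- default_affine(dim(values), spacing)
  structure(
    list(values = values, spacing = as.numeric(spacing),
         affine = as.matrix(affine), laterality = laterality,
         erosion_radius_vox = as.integer(erosion_radius_vox)),
    class = "breast_mask"
  )
}

#' @export
print.breast_mask <- function(x, ...) {
  cat("<breast_mask> ", x$laterality, ", ", sum(x$values), " voxels\n",
      sep = "")
  invisible(x)
}

#' @export
dim.breast_mask <- function(x) dim(x$values)

# shared geometry check
same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$values)[1:3], dim(b$values)[1:3]) &&
    max(abs(a$affine - b$affine)) < tol
}
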
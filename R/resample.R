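#' Resample a mask onto another grid geometry
#'
#' Nearest-neighbour transfer in world coordinates: each target voxel centre
#' is mapped through the target affine and back through the source affine,
#' and takes the value of the nearest source voxel (FALSE outside the source
#' field of view). Nearest-neighbour keeps the mask boolean; an
#' interpolate-then-threshold scheme would introduce an unstated threshold
#' parameter.
#'
#' @param mask a [breast_mask()].
#' @param target a `volume_grid`, `dce_series`, `breast_mask` or a list with
#'   `dim`, `spacing`, `affine` describing the target geometry.
#' @return A [breast_mask()] on the target grid. If the fields of view do
#'   not overlap the result is empty and a warning is raised.
#' @export
resample_mask <- function(mask, target) {
  stopifnot(inherits(mask, "breast_mask"))
  tgt <- target_geometry(target)
  if (identical(dim(mask$values), tgt$dim) &&
      max(abs(mask$affine - tgt$affine)) < 1e-9) {
    out <- mask
    out$spacing <- tgt$spacing
    return(out)
  }
  dm_t <- tgt$dim
  dm_s <- dim(mask$values)
  # voxel(target, 0-based) -> world -> voxel(source, 0-based)
  map <- solve(mask$affine) %*% tgt$affine
  i <- rep.int(seq_len(dm_t[1]) - 1, times = dm_t[2] * dm_t[3])
  j <- rep.int(rep(seq_len(dm_t[2]) - 1, each = dm_t[1]), times = dm_t[3])
  k <- rep(seq_len(dm_t[3]) - 1, each = dm_t[1] * dm_t[2])
  si <- round(map[1, 1] * i + map[1, 2] * j + map[1, 3] * k + map[1, 4])
  sj <- round(map[2, 1] * i + map[2, 2] * j + map[2, 3] * k + map[2, 4])
  sk <- round(map[3, 1] * i + map[3, 2] * j + map[3, 3] * k + map[3, 4])
  inside <- si >= 0 & si < dm_s[1] & sj >= 0 & sj < dm_s[2] &
    sk >= 0 & sk < dm_s[3]
  out <- logical(prod(dm_t))
  if (any(inside)) {
    lin <- si[inside] + dm_s[1] * (sj[inside] + dm_s[2] * sk[inside]) + 1
    out[inside] <- mask$values[lin]
  }
  if (!any(out)) {
    warn("Resampled mask is empty: source and target fields of view may not overlap.")
  }
  breast_mask(array(out, dim = dm_t), spacing = tgt$spacing,
              affine = tgt$affine, laterality = mask$laterality,
              erosion_radius_vox = mask$erosion_radius_vox)
}

target_geometry <- function(target) {
  if (inherits(target, c("volume_grid", "breast_mask"))) {
    list(dim = dim(target$values), spacing = target$spacing,
         affine = target$affine)
  } else if (inherits(target, "dce_series")) {
    list(dim = dim(target$values)[1:3], spacing = target$spacing,
         affine = target$affine)
  } else if (is.list(target) &&
             all(c("dim", "spacing", "affine") %in% names(target))) {
    list(dim = as.integer(target$dim), spacing = as.numeric(target$spacing),
         affine = as.matrix(target$affine))
  } else {
    abort("Unsupported target geometry.", class = "bpemri_format_error")
  }
}
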
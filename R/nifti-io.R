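#' Read a 3D volume from NIfTI
#'
#' @param path path to a `.nii` / `.nii.gz` file with exactly three spatial
#'   dimensions. Files with a non-singleton 4th dimension are refused with a
#'   pointer to [read_dce()].
#' @return A [volume_grid()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "bpemri_format_error")
  }
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) == 4L && dm[4] > 1L) {
    abort(paste0("'", path, "' has a non-spatial 4th dimension (",
                 dm[4], " frames); use read_dce() for dynamic series."),
          class = "bpemri_format_error")
  }
  vals <- array(as.numeric(img), dim = dm[1:3])
  volume_grid(vals, spacing = RNifti::pixdim(img)[1:3],
              affine = matrix(as.numeric(RNifti::xform(img)), 4, 4))
}

#' Write a 3D volume to NIfTI
#'
#' @param v a [volume_grid()] or [breast_mask()] (masks are written uint8).
#' @param path output path (`.nii.gz` recommended).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  is_mask <- inherits(v, "breast_mask")
  stopifnot(is_mask || inherits(v, "volume_grid"))
  vals <- if (is_mask) array(as.integer(v$values), dim(v$values)) else v$values
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- v$spacing
  img <- RNifti::`sform<-`(img, structure(v$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(v$affine, code = 2L))
  RNifti::writeNifti(img, path,
                     datatype = if (is_mask) "uint8" else "double")
  invisible(path)
}

#' Read a 4D DCE series from NIfTI
#'
#' Frame times are taken from a JSON sidecar (`<stem>.json`, key `times_s`)
#' when present, otherwise from the NIfTI time step.
#'
#' @param path path to a 4D NIfTI (time along the 4th dimension).
#' @return A [dce_series()].
#' @export
read_dce <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "bpemri_format_error")
  }
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) != 4L || dm[4] < 2L) {
    abort(paste0("'", path, "' is not a 4D dynamic series ",
                 "(need >= 2 frames along dim 4)."),
          class = "bpemri_format_error")
  }
  sidecar <- sidecar_path(path)
  times_s <- NULL
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    times_s <- meta$times_s
  }
  if (is.null(times_s)) {
    dt <- RNifti::pixdim(img)[4]
    if (!is.finite(dt) || dt <= 0) dt <- 1
    times_s <- (seq_len(dm[4]) - 1) * dt
  }
  dce_series(array(as.numeric(img), dim = dm),
             spacing = RNifti::pixdim(img)[1:3],
             affine = matrix(as.numeric(RNifti::xform(img)), 4, 4),
             times_s = times_s)
}

#' Write a 4D DCE series to NIfTI plus JSON sidecar
#'
#' @param dce a [dce_series()].
#' @param path output `.nii.gz` path; `times_s` goes to `<stem>.json`.
#' @return `path`, invisibly.
#' @export
write_dce <- function(dce, path) {
  stopifnot(inherits(dce, "dce_series"))
  img <- RNifti::asNifti(dce$values)
  dt <- if (length(dce$times_s) > 1) diff(dce$times_s)[1] else 1
  RNifti::pixdim(img) <- c(dce$spacing, dt)
  img <- RNifti::`sform<-`(img, structure(dce$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(dce$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  jsonlite::write_json(list(times_s = dce$times_s,
                            pre_contrast_index = dce$pre_contrast_index),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Read a binary mask from NIfTI
#'
#' @param path NIfTI path; voxel values must be 0/1.
#' @param laterality laterality label to attach.
#' @return A [breast_mask()].
#' @export
read_mask <- function(path, laterality = "bilateral") {
  v <- read_volume(path)
  u <- unique(as.vector(v$values))
  if (!all(u %in% c(0, 1))) {
    abort(sprintf("'%s' is not binary: values outside {0,1} found.", path),
          class = "bpemri_format_error")
  }
  breast_mask(v$values != 0, v$spacing, v$affine, laterality = laterality)
}
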
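#' Estimate and remove a smooth multiplicative bias field
#'
#' Log-domain polynomial surface fit with iterated class reweighting:
#' within the mask, voxels are alternately grouped into `n_classes`
#' intensity classes (on the current corrected log intensities) and a
#' low-order 3D polynomial is fit to the class-mean-removed log
#' intensities. Because tissue-class structure is removed before each
#' surface fit, the polynomial captures only the smooth multiplicative
#' component; class-granularity errors are high-frequency and are rejected
#' by the low-order surface. The estimated field is
#' normalised to mean 1 over the mask so the global intensity scale — and
#' hence any downstream intensity clustering — is unaffected by the
#' correction's gauge. The smoothness model is a polynomial of total degree
#' `max_order` in centred, scaled voxel coordinates.
#'
#' @param volume a [volume_grid()], strictly positive inside the mask
#'   (unless `shift` is set).
#' @param mask a non-empty [breast_mask()] on the same grid.
#' @param max_order maximum total polynomial degree (1 or 2).
#' @param n_classes number of intensity classes removed before each surface
#'   fit; defaults to the segmentation stage's cluster count.
#' @param tol convergence tolerance: maximum fractional change of the
#'   estimated field between iterations.
#' @param max_iter iteration cap.
#' @param shift optional constant added to the volume before the log
#'   transform (for data containing zeros); the shift is removed again
#'   after correction.
#' @return A `bias_field_result` with `corrected` ([volume_grid()]),
#'   `estimated_field` ([volume_grid()], mean 1 over the mask),
#'   `iterations_run` and `converged`.
#' @export
correct_bias <- function(volume, mask, max_order = 2L, n_classes = 7L,
                         tol = 1e-5, max_iter = 30L, shift = 0) {
  stopifnot(inherits(volume, "volume_grid"), inherits(mask, "breast_mask"))
  if (!any(mask$values)) abort("Mask is empty.",
                               class = "bpemri_empty_mask_error")
  if (!same_geometry(volume, mask)) {
    abort("Volume and mask geometries differ.", class = "bpemri_format_error")
  }
  if (!max_order %in% 1:2) abort("`max_order` must be 1 or 2.",
                                 class = "bpemri_parameter_error")
  v <- volume$values + shift
  idx <- which(mask$values)
  x <- v[idx]
  if (any(x <= 0)) {
    abort("Non-positive intensities inside the mask; use `shift`.",
          class = "bpemri_domain_error")
  }

  dm <- dim(v)
  basis_all <- poly_basis_3d(dm, max_order)
  b <- basis_all[idx, , drop = FALSE]
  logx <- log(x)

  field_log <- rep(0, length(idx))
  iterations <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    iterations <- it
    r <- logx - field_log
    cls <- kmeans_1d(r, n_classes)
    resid <- r
    for (cl in unique(cls)) resid[cls == cl] <- r[cls == cl] -
        mean(r[cls == cl])
    # residual relative to class means still contains the (class-mean-
    # removed) field error; accumulate the polynomial fit of it
    fit <- stats::lm.fit(b, resid + field_log - mean(field_log))
    new_log <- as.numeric(b %*% fit$coefficients)
    new_log <- new_log - mean(new_log)
    delta <- max(abs(exp(new_log) - exp(field_log)))
    field_log <- new_log
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }

  coefs <- stats::lm.fit(b, field_log)$coefficients
  coefs[is.na(coefs)] <- 0
  full_log <- as.numeric(basis_all %*% coefs)
  field <- exp(full_log)
  field <- field / mean(field[idx])            # mean exactly 1 over the mask
  corrected <- v / field - shift
  structure(
    list(corrected = volume_grid(corrected, volume$spacing, volume$affine),
         estimated_field = volume_grid(array(field, dm), volume$spacing,
                                       volume$affine),
         iterations_run = iterations, converged = converged),
    class = "bias_field_result"
  )
}

#' @export
print.bias_field_result <- function(x, ...) {
  cat("<bias_field_result> ", x$iterations_run, " iterations, ",
      if (x$converged) "converged" else "NOT converged", "\n", sep = "")
  invisible(x)
}

# Polynomial basis of total degree <= order in centred coordinates scaled
# to [-1, 1]; returned as an n_voxel x n_term matrix.
poly_basis_3d <- function(dm, order) {
  u <- as.vector(slice.index(array(0, dm), 1)) / dm[1] * 2 - 1
  v <- as.vector(slice.index(array(0, dm), 2)) / dm[2] * 2 - 1
  w <- as.vector(slice.index(array(0, dm), 3)) / dm[3] * 2 - 1
  cols <- list(rep(1, length(u)), u, v, w)
  if (order >= 2) {
    cols <- c(cols, list(u * v, u * w, v * w, u^2, v^2, w^2))
  }
  do.call(cbind, cols)
}

# Deterministic 1D k-means (quantile initialisation); returns integer
# class labels. Degenerate (near-constant) data collapse to one class.
kmeans_1d <- function(r, k, max_iter = 50L) {
  if (k < 2 || diff(range(r)) < 1e-8 * max(1, abs(mean(r)))) {
    return(rep(1L, length(r)))
  }
  ctr <- unique(quantile(r, (seq_len(k) - 0.5) / k, names = FALSE, type = 7))
  for (i in seq_len(max_iter)) {
    d <- abs(outer(r, ctr, "-"))
    cls <- max.col(-d, ties.method = "first")
    new_ctr <- vapply(seq_along(ctr),
                      function(c) mean(r[cls == c]), numeric(1))
    new_ctr <- new_ctr[is.finite(new_ctr)]
    if (length(new_ctr) == length(ctr) &&
        max(abs(sort(new_ctr) - ctr)) < 1e-10) break
    ctr <- sort(new_ctr)
  }
  cls
}
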
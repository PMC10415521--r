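#' Fit a fuzzy c-means model to 1D intensities
#'
#' Standard fuzzy c-means on a 1D intensity sample: alternating membership
#' and centroid updates minimising
#' \deqn{J = \sum_i \sum_k u_{ik}^m (x_i - c_k)^2, \qquad \sum_k u_{ik} = 1.}
#' Iteration stops when the relative objective change falls below `tol` or
#' at `max_iter`. Centroids are returned in ascending order with
#' memberships permuted accordingly; the objective trace is recorded per
#' iteration and is non-increasing by construction.
#'
#' Centroids are initialised evenly over the robust intensity range
#' (0.5–99.5 percentiles). Range initialisation seeds every intensity mode
#' regardless of its volume fraction, which quantile initialisation fails
#' to do for a scarce tissue class. `jitter_sd` adds seed-controlled
#' Gaussian jitter for sensitivity analyses; the default is deterministic.
#'
#' @param intensities numeric vector of masked voxel values (n >= K).
#' @param K number of clusters (>= 2); 7 is the pipeline default.
#' @param m fuzziness exponent (> 1); 2 is the conventional default.
#' @param tol relative objective-change convergence threshold.
#' @param max_iter iteration cap; non-convergence is flagged, not an error.
#' @param jitter_sd SD of centroid initialisation jitter, as a fraction of
#'   the initial centroid spacing (0 = deterministic).
#' @param rng_seed seed for the jitter draw.
#' @return An `fcm_model`: `centroids` (ascending), `memberships` (n x K,
#'   rows sum to 1), `objective_trace`, `converged`, `K`, `m`.
#' @export
fit_fcm <- function(intensities, K = 7L, m = 2, tol = 1e-6, max_iter = 300L,
                    jitter_sd = 0, rng_seed = 1L) {
  x <- as.numeric(intensities)
  if (K < 2L) abort("`K` must be >= 2.", class = "bpemri_parameter_error")
  if (m <= 1) abort("`m` must exceed 1.", class = "bpemri_parameter_error")
  if (length(x) < K) abort("Need at least K observations.",
                           class = "bpemri_degenerate_data_error")
  if (length(unique(x)) < K) {
    abort(sprintf("Only %d distinct values for K = %d clusters.",
                  length(unique(x)), K),
          class = "bpemri_degenerate_data_error")
  }
  qs <- quantile(x, c(0.005, 0.995), names = FALSE, type = 7)
  ctr <- seq(qs[1], qs[2], length.out = K)
  if (jitter_sd > 0) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                     envir = globalenv())
    }, add = TRUE)
    set.seed(rng_seed)
    ctr <- ctr + rnorm(K, 0, jitter_sd * diff(ctr)[1])
  }

  expo <- 2 / (m - 1)
  trace <- numeric(0)
  converged <- FALSE
  u <- NULL
  for (it in seq_len(max_iter)) {
    d2 <- outer(x, ctr, "-")^2
    u <- fcm_memberships(d2, expo)
    um <- u^m
    ctr <- as.numeric(crossprod(um, x) / colSums(um))
    j_now <- sum(um * outer(x, ctr, "-")^2)
    trace <- c(trace, j_now)
    if (it > 1 && abs(trace[it - 1] - j_now) <=
        tol * max(trace[it - 1], .Machine$double.eps)) {
      converged <- TRUE
      break
    }
  }
  ord <- order(ctr)
  structure(
    list(centroids = ctr[ord], memberships = u[, ord, drop = FALSE],
         objective_trace = trace, converged = converged,
         K = as.integer(K), m = m),
    class = "fcm_model"
  )
}

# Membership update; zero distances get full membership shared equally
# among the coincident centroids.
fcm_memberships <- function(d2, expo) {
  n <- nrow(d2); K <- ncol(d2)
  zero <- d2 < .Machine$double.xmin
  any_zero <- rowSums(zero) > 0
  inv <- d2^(-expo / 2)
  u <- inv / rowSums(inv)
  if (any(any_zero)) {
    u[any_zero, ] <- zero[any_zero, , drop = FALSE] /
      rowSums(zero[any_zero, , drop = FALSE])
  }
  u
}

#' Evaluate the fuzzy c-means objective
#'
#' @param x intensity vector.
#' @param memberships n x K matrix, rows summing to 1.
#' @param centroids length-K centroid vector.
#' @param m fuzziness exponent.
#' @return The objective J.
#' @export
fcm_objective <- function(x, memberships, centroids, m = 2) {
  sum(memberships^m * outer(as.numeric(x), centroids, "-")^2)
}

#' @export
print.fcm_model <- function(x, ...) {
  cat("<fcm_model> K = ", x$K, ", centroids: ",
      paste(signif(x$centroids, 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @describeIn fit_fcm one row per cluster: centroid, hard-assigned voxel
#'   count, total membership mass.
#' @param x an `fcm_model`.
#' @param ... unused.
#' @method tidy fcm_model
#' @export
tidy.fcm_model <- function(x, ...) {
  hard <- hard_assign(x$memberships)
  tibble(
    cluster = seq_len(x$K),
    centroid = x$centroids,
    n_voxels = as.integer(tabulate(hard, x$K)),
    membership_mass = colSums(x$memberships)
  )
}

#' @describeIn fit_fcm one-row model summary.
#' @method glance fcm_model
#' @export
glance.fcm_model <- function(x, ...) {
  tibble(K = x$K, m = x$m, n = nrow(x$memberships),
         objective = tail(x$objective_trace, 1),
         iterations = length(x$objective_trace), converged = x$converged)
}

# Hard assignment by maximum membership; ties break to the lower cluster
# index (ties.method = "first" on the original column order, which is
# ascending-centroid order).
hard_assign <- function(u) {
  max.col(u, ties.method = "first")
}

# Resolve a cluster-selection rule to cluster indices (ascending-centroid
# order). Rules: "lowest:k", "highest:k", "gap:high", "gap:low", or an
# explicit integer vector.
resolve_selection <- function(rule, centroids) {
  K <- length(centroids)
  if (is.numeric(rule)) {
    sel <- as.integer(rule)
    if (length(sel) == 0 || any(sel < 1L) || any(sel > K)) {
      abort("Explicit cluster selection outside 1..K or empty.",
            class = "bpemri_configuration_error")
    }
    return(sort(unique(sel)))
  }
  if (grepl("^lowest:[0-9]+$", rule)) {
    k <- as.integer(sub("^lowest:", "", rule))
    if (k < 1) abort("Selection count must be >= 1.",
                     class = "bpemri_configuration_error")
    return(seq_len(min(k, K)))      # clamp when K was reduced for the data
  }
  if (grepl("^highest:[0-9]+$", rule)) {
    k <- as.integer(sub("^highest:", "", rule))
    if (k < 1) abort("Selection count must be >= 1.",
                     class = "bpemri_configuration_error")
    return(seq.int(K - min(k, K) + 1L, K))
  }
  if (rule %in% c("gap:high", "gap:low")) {
    gaps <- diff(centroids)
    g <- which.max(gaps)
    return(if (rule == "gap:high") seq.int(g + 1L, K) else seq_len(g))
  }
  abort(sprintf("Unknown cluster-selection rule '%s'.", rule),
        class = "bpemri_configuration_error")
}

#' Segment fibro-glandular tissue within one breast
#'
#' Fits a fuzzy c-means model to the (bias-corrected) intensities inside
#' the given breast mask, hard-assigns each voxel to its maximum-membership
#' cluster (ties to the lower index), and labels as fibro-glandular the
#' union of the selected clusters. On non-fat-suppressed T2w images FGT is
#' dark, so the default selects the three lowest-centroid clusters of
#' seven; `selection` accepts `"lowest:k"`, `"highest:k"`, `"gap:high"`,
#' `"gap:low"` or an explicit cluster index set for per-case fine-tuning.
#'
#' @param corrected a [volume_grid()] (typically bias-corrected).
#' @param breast a non-empty [breast_mask()] for one breast.
#' @param K,m,tol,max_iter,jitter_sd,rng_seed passed to [fit_fcm()].
#' @param selection cluster-selection rule (see above).
#' @return A `tissue_segmentation`: `fgt_mask` ([breast_mask()]),
#'   `selected_clusters`, `model` (`fcm_model`), `laterality`.
#' @export
segment_fgt <- function(corrected, breast, K = 7L, m = 2,
                        selection = "lowest:3", tol = 1e-6, max_iter = 300L,
                        jitter_sd = 0, rng_seed = 1L) {
  stopifnot(inherits(corrected, "volume_grid"), inherits(breast, "breast_mask"))
  if (!any(breast$values)) abort("Breast mask is empty.",
                                 class = "bpemri_empty_mask_error")
  if (!same_geometry(corrected, breast)) {
    abort("Volume and mask geometries differ.", class = "bpemri_format_error")
  }
  idx <- which(breast$values)
  x <- corrected$values[idx]
  # idealised (noise-free) data can carry fewer distinct intensities than
  # K; fit with the largest supportable cluster count instead of failing
  n_distinct <- length(unique(x))
  K_eff <- min(as.integer(K), n_distinct)
  if (K_eff < 2L) {
    abort("Mask intensities are constant: nothing to cluster.",
          class = "bpemri_degenerate_data_error")
  }
  if (K_eff < K) {
    inform(sprintf("Reduced cluster count to %d (only %d distinct values).",
                   K_eff, n_distinct))
    # keep count-based selection rules proportionate to the reduced K
    # (e.g. lowest:3 of 7 becomes lowest:1 of 2), never selecting all
    # clusters implicitly
    if (is.character(selection) &&
        grepl("^(lowest|highest):[0-9]+$", selection)) {
      parts <- strsplit(selection, ":", fixed = TRUE)[[1]]
      k_new <- max(1L, min(K_eff - 1L,
                           as.integer(round(as.integer(parts[2]) *
                                              K_eff / K))))
      selection <- paste0(parts[1], ":", k_new)
    }
  }
  model <- fit_fcm(x, K = K_eff, m = m, tol = tol,
                   max_iter = max_iter, jitter_sd = jitter_sd,
                   rng_seed = rng_seed)
  sel <- resolve_selection(selection, model$centroids)
  hard <- hard_assign(model$memberships)
  fgt <- array(FALSE, dim(breast$values))
  fgt[idx[hard %in% sel]] <- TRUE
  structure(
    list(fgt_mask = breast_mask(fgt, breast$spacing, breast$affine,
                                breast$laterality),
         selected_clusters = sel, model = model,
         laterality = breast$laterality),
    class = "tissue_segmentation"
  )
}

#' @export
print.tissue_segmentation <- function(x, ...) {
  cat("<tissue_segmentation> ", x$laterality, ", ", sum(x$fgt_mask$values),
      " FGT voxels, clusters {", paste(x$selected_clusters, collapse = ","),
      "} of ", x$model$K, "\n", sep = "")
  invisible(x)
}

#' Fibro-glandular volume and MRI breast density
#'
#' Fibro-glandular volume is the FGT voxel count times the voxel volume;
#' MRBD is the percentage of the breast volume occupied by FGT.
#'
#' @param seg a `tissue_segmentation` (or [breast_mask()] of FGT).
#' @param breast the [breast_mask()] the segmentation lives in.
#' @return One-row tibble: `laterality`, `fgt_volume_cc`, `breast_volume_cc`,
#'   `mrbd_pct`.
#' @export
compute_density <- function(seg, breast) {
  fgt <- if (inherits(seg, "tissue_segmentation")) seg$fgt_mask else seg
  stopifnot(inherits(fgt, "breast_mask"), inherits(breast, "breast_mask"))
  if (!same_geometry(fgt, breast)) {
    abort("Segmentation and breast mask geometries differ.",
          class = "bpemri_format_error")
  }
  n_breast <- sum(breast$values)
  if (n_breast == 0) {
    abort("Breast mask is empty: density undefined.",
          class = "bpemri_empty_mask_error")
  }
  vox_cc <- voxel_volume_cc(breast$spacing)
  n_fgt <- sum(fgt$values & breast$values)
  tibble(
    laterality = breast$laterality,
    fgt_volume_cc = n_fgt * vox_cc,
    breast_volume_cc = n_breast * vox_cc,
    mrbd_pct = 100 * n_fgt / n_breast
  )
}
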
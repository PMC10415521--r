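#' Bland-Altman plot
#'
#' Mean of the paired right/left measurements against their difference,
#' with the bias (solid) and the limits of agreement (dashed) at bias
#' plus/minus 1.96 sample SD of the differences.
#'
#' @param object a [bland_altman()] result.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$mean_pair, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$bias, linewidth = 0.6) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of right and left measurements",
                  y = "Difference (right - left)",
                  title = sprintf("Bias %.3g, RPC %.3g (n = %d)",
                                  object$bias, object$rpc, object$n_pairs)) +
    ggplot2::theme_minimal()
}

#' Histogram of a voxelwise BPE distribution
#'
#' @param object a `bpe_result` from [compute_bpe_map()].
#' @param bins histogram bin count.
#' @param ... unused.
#' @return A ggplot with the median and quartiles marked.
#' @method autoplot bpe_result
#' @export
autoplot.bpe_result <- function(object, bins = 60, ...) {
  s <- object$summary
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$bpe_pct)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::geom_vline(xintercept = s$median, linewidth = 0.6) +
    ggplot2::geom_vline(xintercept = c(s$q1, s$q3), linetype = "dashed") +
    ggplot2::labs(
      x = "Voxel enhancement (%)", y = "Voxels",
      title = sprintf(
        "%s breast BPE: median %.1f%%, IQR %.1f%%, kurtosis %.2f",
        object$laterality, s$median, s$iqr, s$kurtosis)) +
    ggplot2::theme_minimal()
}

#' Axial slice of a volume with optional mask overlays
#'
#' Quick-look display used in the vignette: one axial (superior-inferior)
#' slice of a volume with up to two mask outlines overlaid.
#'
#' @param volume a [volume_grid()].
#' @param k slice index along the third axis (default: middle).
#' @param mask,mask2 optional [breast_mask()]s to overlay.
#' @return A ggplot raster.
#' @export
plot_slice <- function(volume, k = NULL, mask = NULL, mask2 = NULL) {
  stopifnot(inherits(volume, "volume_grid"))
  dm <- dim(volume$values)
  if (is.null(k)) k <- ceiling(dm[3] / 2)
  sl <- volume$values[, , k]
  df <- tidyr::expand_grid(i = seq_len(dm[1]), j = seq_len(dm[2]))
  df$intensity <- as.vector(sl)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                        fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  add_overlay <- function(p, m, colour) {
    msl <- m$values[, , k]
    if (!any(msl)) return(p)
    dm2 <- df[as.vector(msl), c("i", "j")]
    p + ggplot2::geom_tile(data = dm2,
                           ggplot2::aes(x = .data$j, y = .data$i),
                           fill = colour, alpha = 0.35, inherit.aes = FALSE)
  }
  if (!is.null(mask)) p <- add_overlay(p, mask, "yellow")
  if (!is.null(mask2)) p <- add_overlay(p, mask2, "red")
  p
}
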
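#' Pipeline stage configuration
#'
#' Bundles the tunable parameters of every stage with their defaults:
#' region-growing tolerance in intensity units, erosion ball radius in
#' voxels, bias polynomial order, cluster count K = 7 with fuzziness m = 2,
#' the T2w FGT selection rule (three lowest-centroid clusters) and the
#' fat-suppressed parenchyma rule (clusters above the largest centroid
#' gap), and the BPE denominator floor.
#'
#' @param seeds optional voxel seed matrix for [region_grow()]; `NULL`
#'   uses [auto_seeds()].
#' @param tolerance region-growing tolerance (intensity units).
#' @param erode_radius_vox erosion ball radius (voxels).
#' @param bias_order,bias_n_classes bias-correction polynomial order and
#'   class count.
#' @param k_clusters,fuzziness FCM cluster count and exponent.
#' @param t2w_selection,dce_selection cluster-selection rules for FGT on
#'   T2w and parenchyma on the pre-contrast DCE frame.
#' @param denominator_floor_frac BPE denominator floor (fraction of the
#'   parenchymal pre-contrast median).
#' @param rng_seed cohort-level seed; per-subject seeds are derived from it
#'   and the subject id, so results do not depend on manifest order.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seeds = NULL, tolerance = 240,
                            erode_radius_vox = 2L, bias_order = 2L,
                            bias_n_classes = 7L, k_clusters = 7L,
                            fuzziness = 2, t2w_selection = "lowest:3",
                            dce_selection = "gap:high",
                            denominator_floor_frac = 0.01,
                            rng_seed = 1L) {
  structure(
    list(seeds = seeds, tolerance = tolerance,
         erode_radius_vox = as.integer(erode_radius_vox),
         bias_order = as.integer(bias_order),
         bias_n_classes = as.integer(bias_n_classes),
         k_clusters = as.integer(k_clusters), fuzziness = fuzziness,
         t2w_selection = t2w_selection, dce_selection = dce_selection,
         denominator_floor_frac = denominator_floor_frac,
         rng_seed = as.integer(rng_seed)),
    class = "pipeline_config"
  )
}

# Deterministic per-subject seed below 2^31, independent of cohort order.
subject_seed <- function(cohort_seed, subject_id) {
  h <- sum(utf8ToInt(as.character(subject_id)) *
             (31^(seq_along(utf8ToInt(as.character(subject_id))) %% 7)))
  as.integer((as.numeric(cohort_seed) * 48271 + h) %% 2147483647)
}

#' Analyse one subject: masks, density, BPE, per laterality
#'
#' Executes the full stage chain — whole-breast masking (region grow +
#' erode + laterality split) on the T2w volume, bias-field correction,
#' per-breast FGT segmentation and density, mask resampling to the DCE
#' grid, parenchyma segmentation on the pre-contrast frame, MTP selection,
#' and the voxelwise BPE map — and returns one results row per laterality.
#' A missing DCE series still yields density metrics with the BPE fields
#' left `NA`; stage errors are caught and recorded in the `error` column
#' (skip-and-log), so a cohort run continues past a failing subject.
#'
#' @param t2w non-fat-suppressed T2w volume: a [volume_grid()] or NIfTI
#'   path.
#' @param dce dynamic series: a [dce_series()], NIfTI path, or `NULL`.
#' @param cfg a [pipeline_config()].
#' @param subject_id subject identifier carried into the results.
#' @param exclusion optional [breast_mask()] (or path) on the DCE grid
#'   marking regions to drop from the parenchyma (fat-suppression
#'   failure).
#' @return Tibble with one row per laterality (see `results table` fields
#'   in the package vignette).
#' @export
run_subject <- function(t2w, dce = NULL, cfg = pipeline_config(),
                        subject_id = "subject", exclusion = NULL) {
  t2w <- load_volume_input(t2w)
  if (!is.null(dce) && is.character(dce)) {
    dce <- tryCatch(read_dce(dce), error = function(e) {
      warn(sprintf("Subject %s: DCE unreadable (%s); BPE skipped.",
                   subject_id, conditionMessage(e)))
      NULL
    })
  }
  if (!is.null(exclusion) && is.character(exclusion)) {
    exclusion <- read_mask(exclusion)
  }
  seed <- subject_seed(cfg$rng_seed, subject_id)

  base_row <- function(lat) {
    tibble(subject = subject_id, laterality = lat,
           breast_volume_cc = NA_real_, fgt_volume_cc = NA_real_,
           mrbd_pct = NA_real_, bpe_median_pct = NA_real_,
           bpe_q1_pct = NA_real_, bpe_q3_pct = NA_real_,
           bpe_iqr_pct = NA_real_, bpe_skewness = NA_real_,
           bpe_kurtosis = NA_real_, n_parenchyma_voxels = NA_integer_,
           mtp_index = NA_integer_, n_dropped_denominator = NA_integer_,
           mask_voxels = NA_integer_, fcm_converged = NA,
           bias_converged = NA, rng_seed = seed, error = NA_character_)
  }

  result <- tryCatch({
    masks <- mask_breast(t2w, seeds = cfg$seeds, tolerance = cfg$tolerance,
                         erode_radius_vox = cfg$erode_radius_vox)
    bias <- correct_bias(t2w, masks$bilateral, max_order = cfg$bias_order,
                         n_classes = cfg$bias_n_classes)
    rows <- purrr::map(c("left", "right"), function(lat) {
      row <- base_row(lat)
      side <- masks[[lat]]
      row$mask_voxels <- sum(side$values)
      row$bias_converged <- bias$converged
      seg <- segment_fgt(bias$corrected, side, K = cfg$k_clusters,
                         m = cfg$fuzziness, selection = cfg$t2w_selection,
                         rng_seed = seed)
      dens <- compute_density(seg, side)
      row$fgt_volume_cc <- dens$fgt_volume_cc
      row$breast_volume_cc <- dens$breast_volume_cc
      row$mrbd_pct <- dens$mrbd_pct
      row$fcm_converged <- seg$model$converged
      if (!is.null(dce)) {
        bpe_row <- tryCatch({
          side_dce <- resample_mask(side, dce)
          par <- segment_parenchyma_precontrast(
            dce, side_dce, exclusion = exclusion, K = cfg$k_clusters,
            m = cfg$fuzziness, selection = cfg$dce_selection,
            rng_seed = seed)
          bpe <- compute_bpe_map(
            dce, par, denominator_floor_frac = cfg$denominator_floor_frac)
          s <- bpe$summary
          list(median = s$median, q1 = s$q1, q3 = s$q3, iqr = s$iqr,
               skewness = s$skewness, kurtosis = s$kurtosis, n = s$n,
               mtp = bpe$mtp_index, dropped = bpe$n_dropped_denominator,
               err = NA_character_)
        }, error = function(e) {
          list(median = NA_real_, q1 = NA_real_, q3 = NA_real_,
               iqr = NA_real_, skewness = NA_real_, kurtosis = NA_real_,
               n = NA_integer_, mtp = NA_integer_, dropped = NA_integer_,
               err = conditionMessage(e))
        })
        row$bpe_median_pct <- bpe_row$median
        row$bpe_q1_pct <- bpe_row$q1
        row$bpe_q3_pct <- bpe_row$q3
        row$bpe_iqr_pct <- bpe_row$iqr
        row$bpe_skewness <- bpe_row$skewness
        row$bpe_kurtosis <- bpe_row$kurtosis
        row$n_parenchyma_voxels <- bpe_row$n
        row$mtp_index <- bpe_row$mtp
        row$n_dropped_denominator <- bpe_row$dropped
        row$error <- bpe_row$err
      }
      row
    })
    dplyr::bind_rows(rows)
  }, error = function(e) {
    rows <- dplyr::bind_rows(base_row("left"), base_row("right"))
    rows$error <- conditionMessage(e)
    rows
  })
  result
}

load_volume_input <- function(x) {
  if (inherits(x, "volume_grid")) return(x)
  if (is.character(x)) return(read_volume(x))
  abort("Expected a volume_grid or a NIfTI path.",
        class = "bpemri_format_error")
}

#' Run a cohort manifest and assemble the statistics report
#'
#' Runs [run_subject()] for every manifest row and builds the study's
#' statistics layer: a per-metric right-breast group comparison
#' (median and quartiles per group, test and p-value), Bland-Altman
#' right/left agreement for fibro-glandular volume, MRBD and median BPE,
#' paired right-vs-left tests, and — when the manifest contains repeated
#' analyses of the same subject (a `repeat_id` column) — repeatability
#' coefficients of variation.
#'
#' @param manifest data frame with columns `subject`, `t2w`, `dce`
#'   (paths or in-memory objects in list columns), optional `group`,
#'   `age`, `weight`, `exclusion`, `repeat_id`.
#' @param cfg a [pipeline_config()].
#' @return A list: `results` (tibble, one row per subject x laterality)
#'   and `report` (list of `group_comparison`, `left_right_agreement`,
#'   `left_right_tests`, `repeatability_cv`).
#' @export
run_cohort <- function(manifest, cfg = pipeline_config()) {
  if (is.null(manifest) || nrow(manifest) == 0) {
    abort("Empty manifest.", class = "bpemri_configuration_error")
  }
  manifest <- as_tibble(manifest)
  get_cell <- function(col, i) {
    if (!col %in% names(manifest)) return(NULL)
    v <- manifest[[col]]
    if (is.list(v)) v[[i]] else v[[i]]
  }
  results <- purrr::map(seq_len(nrow(manifest)), function(i) {
    sid <- as.character(manifest$subject[i])
    rid <- if ("repeat_id" %in% names(manifest)) {
      as.character(manifest$repeat_id[i])
    } else {
      "1"
    }
    rows <- run_subject(get_cell("t2w", i), get_cell("dce", i), cfg = cfg,
                        subject_id = if (rid == "1") sid else
                          paste0(sid, "#", rid),
                        exclusion = get_cell("exclusion", i))
    rows$subject <- sid
    rows$repeat_id <- rid
    for (col in c("group", "age", "weight")) {
      if (col %in% names(manifest)) rows[[col]] <- manifest[[col]][i]
    }
    rows
  }) |> dplyr::bind_rows()

  report <- cohort_report(results)
  list(results = results, report = report)
}

# The statistics layer over a persisted results table; everything here is
# recomputable from the table alone.
cohort_report <- function(results) {
  metrics <- c("fgt_volume_cc", "mrbd_pct", "bpe_median_pct")
  primary <- results[results$repeat_id == "1", , drop = FALSE]

  # right/left agreement over subjects with both sides analysable
  wide <- tidyr::pivot_wider(
    primary[, c("subject", "laterality", metrics)],
    names_from = "laterality", values_from = dplyr::all_of(metrics))
  ba <- list(); lr_tests <- list()
  for (mname in metrics) {
    r <- wide[[paste0(mname, "_right")]]
    l <- wide[[paste0(mname, "_left")]]
    ok <- is.finite(r) & is.finite(l)
    if (sum(ok) >= 2) {
      ba[[mname]] <- bland_altman(tibble(r = r[ok], l = l[ok]), r, l)
      lr_tests[[mname]] <- dplyr::bind_rows(
        paired_t(r[ok], l[ok]),
        tryCatch(wilcoxon_signed_rank(r[ok], l[ok]),
                 error = function(e) NULL))
      lr_tests[[mname]]$metric <- mname
    }
  }

  # group comparison on the right breast only
  group_comparison <- NULL
  if ("group" %in% names(results) &&
      length(unique(stats::na.omit(primary$group))) == 2) {
    right <- primary[primary$laterality == "right", , drop = FALSE]
    bpe_metrics <- c("bpe_median_pct", "bpe_q1_pct", "bpe_q3_pct",
                     "bpe_skewness", "bpe_kurtosis")
    all_metrics <- c(metrics[1:2], intersect(bpe_metrics, names(right)))
    group_comparison <- withCallingHandlers(
      cohort_compare(right, all_metrics, group),
      warning = function(w) invokeRestart("muffleWarning"))
  }

  # repeatability CVs when repeated analyses exist
  repeatability_cv <- NULL
  if (length(unique(results$repeat_id)) > 1) {
    rep_right <- results[results$laterality == "right", , drop = FALSE]
    repeatability_cv <- purrr::map(
      setNames(metrics, metrics),
      function(mname) {
        d <- rep_right[is.finite(rep_right[[mname]]),
                       c("subject", mname), drop = FALSE]
        names(d)[2] <- "value"
        tryCatch(coefficient_of_variation(d, value, subject),
                 error = function(e) NULL)
      })
  }

  list(group_comparison = group_comparison,
       left_right_agreement = ba,
       left_right_tests = dplyr::bind_rows(lr_tests),
       repeatability_cv = repeatability_cv)
}

#' Write a cohort run to disk
#'
#' @param run result of [run_cohort()].
#' @param dir output directory.
#' @return `dir`, invisibly. Writes `results.csv`, `results.json` and a
#'   `report.json` with the group-comparison table, agreement statistics
#'   and CVs.
#' @export
write_cohort <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$results, file.path(dir, "results.csv"),
                   row.names = FALSE)
  jsonlite::write_json(run$results, file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  rep <- run$report
  rep_json <- list(
    group_comparison = rep$group_comparison,
    left_right_agreement = purrr::map(rep$left_right_agreement, glance),
    left_right_tests = rep$left_right_tests,
    repeatability_cv = purrr::map(
      purrr::compact(rep$repeatability_cv %||% list()), glance)
  )
  jsonlite::write_json(rep_json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
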
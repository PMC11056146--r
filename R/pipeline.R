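# End-to-end orchestration: phantom -> map fitting -> WMH segmentation ->
# four-class change masks -> per-class mean signatures -> statistical
# battery.
#
# NODDI parameters are measured at baseline only (the follow-up protocol
# carries no multishell acquisition); FA, MD and T1 are measured at both
# visits and enter the longitudinal tests. MD is reported in 1e-3 mm^2/s
# and T1 in seconds throughout the result tables.

#' Run configuration for the synthetic-cohort analysis
#'
#' @param spec a \code{phantom_spec}.
#' @param n_subjects cohort size (>= 2).
#' @param seed master seed; per-subject seeds derive from it.
#' @param long_params parameters measured at both visits.
#' @param fit_noddi whether to fit baseline NODDI maps (slow; off by
#'   default).
#' @param seg_config a \code{segmentation_config}.
#' @param min_cluster cluster-size threshold applied before resampling.
#' @param connectivity cluster connectivity (26 default).
#' @return a named list used by \code{run_subject}/\code{run_cohort}.
#' @export
run_config <- function(spec = phantom_spec(), n_subjects = 20L,
                       seed = 1L, long_params = c("FA", "MD", "T1"),
                       fit_noddi = FALSE,
                       seg_config = segmentation_config(),
                       min_cluster = 5L, connectivity = 26L) {
  stopifnot(n_subjects >= 2)
  list(spec = spec, n_subjects = n_subjects, seed = seed,
       long_params = long_params, fit_noddi = fit_noddi,
       seg_config = seg_config, min_cluster = min_cluster,
       connectivity = connectivity)
}

#' Process one subject end-to-end
#'
#' Generates the phantom, segments WMHs on both visits, derives NAWM by
#' subtraction, builds the four change classes, records structural-space
#' volumes (pre-filter), filters small clusters, resamples the masks onto
#' the diffusion grid, fits the quantitative maps and measures per-class
#' means.
#'
#' @param config from \code{run_config}.
#' @param subject_seed integer seed for this subject.
#' @param subject_id identifier attached to the output rows.
#' @return list with \code{measures} (long data frame: subject, parameter,
#'   class, timepoint, value), \code{volumes}, \code{dice} (segmentation
#'   overlap vs ground truth per visit), \code{truth} (subject truth
#'   table), and the mask voxel counts.
#' @export
run_subject <- function(config, subject_seed, subject_id = subject_seed) {
  ph <- make_subject_phantom(config$spec, subject_seed)
  vox_s <- ph$voxel_mm_structural
  vox_d <- ph$voxel_mm_diffusion

  seg <- lapply(list(bl = ph$flair_bl, fu = ph$flair_fu), function(fl)
    segment_wmh(fl, ph$brain_mask, ph$template_prior, config$seg_config))
  seg <- lapply(seg, function(m) m & !ph$stroke_mask)
  nawm <- lapply(seg, function(m)
    derive_nawm(ph$wm_mask, m, ph$stroke_mask))

  dice <- c(bl = dice_coefficient(seg$bl, ph$labels_bl == LABEL_WMH),
            fu = dice_coefficient(seg$fu, ph$labels_fu == LABEL_WMH))

  classes <- change_classes(nawm$bl, seg$bl, nawm$fu, seg$fu)
  volumes <- class_volumes(classes, vox_s)
  filtered <- lapply(classes, filter_small_clusters,
                     min_size = config$min_cluster,
                     connectivity = config$connectivity)
  shp_d <- ph$dwi_bl$grid_shape
  masks_d <- lapply(filtered, resample_nn, src_voxel_mm = vox_s,
                    target_shape = shp_d, target_voxel_mm = vox_d)

  rows <- list()
  add <- function(par, tp, means) {
    rows[[length(rows) + 1L]] <<- data.frame(
      subject = subject_id, parameter = par,
      class = names(means), timepoint = tp, value = as.numeric(means),
      stringsAsFactors = FALSE)
  }

  union_d <- Reduce(`|`, masks_d)
  if (any(c("FA", "MD") %in% config$long_params)) {
    for (tp in c("bl", "fu")) {
      dw <- if (tp == "bl") ph$dwi_bl else ph$dwi_fu
      fit <- fit_dti_map(dw$signals, dw$voxels, shp_d, union_d, dw$scheme)
      if ("FA" %in% config$long_params)
        add("FA", tp, class_means(fit$fa, masks_d, fit$converged))
      if ("MD" %in% config$long_params)
        add("MD", tp, class_means(fit$md * 1e3, masks_d, fit$converged))
    }
  }
  if ("T1" %in% config$long_params) {
    # baseline HIFI estimates B1 jointly; the sparse follow-up protocol
    # re-uses that B1 map (see fit_despot1_hifi)
    union_s <- Reduce(`|`, filtered)
    fit_bl <- fit_t1_map(ph$spgr_ir_bl$signals, union_s,
                         ph$spgr_ir_bl$protocol)
    add("T1", "bl", class_means(fit_bl$t1, filtered, fit_bl$converged))
    fit_fu <- fit_t1_map(ph$spgr_ir_fu$signals, union_s,
                         ph$spgr_ir_fu$protocol, b1_fixed = fit_bl$b1)
    add("T1", "fu", class_means(fit_fu$t1, filtered, fit_fu$converged))
  }
  if (isTRUE(config$fit_noddi)) {
    fit <- fit_noddi_map(ph$dwi_bl$signals, ph$dwi_bl$voxels, shp_d,
                         union_d, ph$dwi_bl$scheme)
    add("NDI", "bl", class_means(fit$ndi, masks_d, fit$converged))
    add("ODI", "bl", class_means(fit$odi, masks_d, fit$converged))
    add("FWF", "bl", class_means(fit$fwf, masks_d, fit$converged))
  }

  list(measures = do.call(rbind, rows),
       volumes = cbind(subject = subject_id, volumes),
       dice = dice,
       truth = cbind(subject = subject_id, ph$truth),
       mask_voxels = vapply(masks_d, sum, numeric(1)))
}

#' Run the full synthetic-cohort analysis
#'
#' Processes every subject (seeds derived from the master seed), assembles
#' the cohort table, and runs the statistical battery: GG-corrected
#' repeated-measures ANOVAs with Tukey HSD contrasts per parameter and
#' timepoint, and paired t tests of 1-year change with a single Holm
#' family across all (parameter, class) rows. The expected direction of
#' each longitudinal effect is taken from the cohort's own ground truth
#' and compared against the fitted estimates in the sign-pattern summary.
#'
#' @param config from \code{run_config}.
#' @return list: \code{cohort} (long table), \code{truth}, \code{anova},
#'   \code{tukey}, \code{paired}, \code{volumes}, \code{dice},
#'   \code{sign_summary}, \code{seeds}.
#' @export
run_cohort <- function(config) {
  seeds <- cohort_subject_seeds(config$n_subjects, config$seed)
  subj <- lapply(seq_len(config$n_subjects), function(i)
    run_subject(config, seeds[i], subject_id = i))
  cohort <- do.call(rbind, lapply(subj, `[[`, "measures"))
  truth <- do.call(rbind, lapply(subj, `[[`, "truth"))
  volumes <- do.call(rbind, lapply(subj, `[[`, "volumes"))
  dice <- do.call(rbind, lapply(subj, `[[`, "dice"))

  noddi_params <- if (isTRUE(config$fit_noddi))
    c("NDI", "ODI", "FWF") else character(0)
  battery <- run_stats_battery(cohort,
                               cross_params = config$long_params,
                               baseline_only_params = noddi_params,
                               long_params = config$long_params)

  expected <- truth_effects(truth)
  sign_summary <- if (!is.null(battery$paired))
    sign_pattern_summary(battery$paired, expected) else NULL

  c(battery,
    list(cohort = cohort, truth = truth, volumes = volumes, dice = dice,
         sign_summary = sign_summary, seeds = seeds, config = config))
}

#' Ground-truth longitudinal effects from a cohort truth table
#'
#' Mean (over subjects) of the true follow-up minus baseline class means,
#' per parameter and class.
#'
#' @param truth row-bound subject truth tables.
#' @return data frame: parameter, class, expected_effect.
#' @export
truth_effects <- function(truth) {
  wide_bl <- truth[truth$timepoint == "bl", ]
  wide_fu <- truth[truth$timepoint == "fu", ]
  key <- c("subject", "class", "parameter")
  m <- merge(wide_bl, wide_fu, by = key, suffixes = c("_bl", "_fu"))
  m$d <- m$true_mean_fu - m$true_mean_bl
  agg <- stats::aggregate(d ~ parameter + class, data = m, FUN = mean)
  names(agg)[names(agg) == "d"] <- "expected_effect"
  agg
}
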
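# WMH segmentation from a FLAIR-like volume by hierarchical intensity
# thresholding: candidate voxels exceed the brain mean by a multiple of the
# brain SD, a lesion-probability template vetoes implausible locations, the
# candidate indicator is Gaussian-smoothed, and a final intensity Z-score
# floor removes marginal voxels.

#' Segmentation configuration
#'
#' @param threshold_sd candidate threshold in brain-SD units above the
#'   brain mean (default 1.69).
#' @param z_floor minimum intensity Z score retained after smoothing
#'   (default 0.95).
#' @param smooth_sigma_vox Gaussian sigma applied to the candidate
#'   indicator, voxels (default 0.5; 0 disables).
#' @param smooth_keep support level at which the smoothed candidate
#'   indicator is re-binarized. The default 0.25 sits below the kernel's
#'   own center weight, so an in-mask hole surrounded by candidates is
#'   filled while a voxel with neither self- nor neighbourhood support is
#'   dropped.
#' @param prior_floor candidates with template probability below this are
#'   vetoed (default 0.1).
#' @return object of class \code{segmentation_config}.
#' @export
segmentation_config <- function(threshold_sd = 1.69, z_floor = 0.95,
                                smooth_sigma_vox = 0.5, smooth_keep = 0.25,
                                prior_floor = 0.1) {
  stopifnot(threshold_sd > 0, z_floor >= 0, smooth_sigma_vox >= 0,
            smooth_keep > 0, smooth_keep < 1,
            prior_floor >= 0, prior_floor <= 1)
  structure(list(threshold_sd = threshold_sd, z_floor = z_floor,
                 smooth_sigma_vox = smooth_sigma_vox,
                 smooth_keep = smooth_keep, prior_floor = prior_floor),
            class = "segmentation_config")
}

#' Mean and SD of brain-tissue intensity
#'
#' @param vol intensity volume.
#' @param brain_mask logical volume; must contain at least 2 voxels.
#' @return list with \code{mean} and \code{sd} (sample SD).
#' @export
brain_stats <- function(vol, brain_mask) {
  stopifnot(identical(dim(vol), dim(brain_mask)))
  n <- sum(brain_mask)
  if (n < 2L)
    stop("brain mask must contain at least 2 voxels for a sample SD")
  x <- vol[brain_mask]
  list(mean = mean(x), sd = sd(x))
}

#' Segment WMHs by hierarchical thresholding
#'
#' Pipeline: (1) candidates are voxels with intensity above
#' mean + threshold_sd * SD of the brain tissue; (2) candidates with
#' template prior below \code{prior_floor} are vetoed; (3) the candidate
#' indicator is Gaussian-smoothed and re-binarized at 0.5, which fills
#' interior holes and drops isolated voxels (the template veto is
#' re-applied); (4) voxels with intensity Z score below \code{z_floor}
#' (same brain statistics) are dropped. The output is a binary mask within
#' the brain mask.
#'
#' @param vol FLAIR-like intensity volume.
#' @param brain_mask logical brain mask (non-degenerate intensity SD
#'   required).
#' @param template_prior lesion-probability volume in [0, 1] on the same
#'   grid.
#' @param config a \code{segmentation_config}.
#' @return logical WMH mask.
#' @export
segment_wmh <- function(vol, brain_mask, template_prior,
                        config = segmentation_config()) {
  stopifnot(identical(dim(vol), dim(brain_mask)),
            identical(dim(vol), dim(template_prior)))
  if (!any(brain_mask)) stop("brain mask is empty")
  if (any(template_prior < -1e-9) || any(template_prior > 1 + 1e-9))
    stop("template prior must lie in [0, 1]")
  bs <- brain_stats(vol, brain_mask)
  if (bs$sd <= 0) stop("degenerate brain intensity SD")
  cand <- brain_mask & (vol > bs$mean + config$threshold_sd * bs$sd)
  cand <- cand & (template_prior >= config$prior_floor)
  if (config$smooth_sigma_vox > 0) {
    sm <- gaussian_smooth3d(cand * 1, config$smooth_sigma_vox)
    cand <- brain_mask & (sm > config$smooth_keep) &
      (template_prior >= config$prior_floor)
  }
  z <- (vol - bs$mean) / bs$sd
  cand & (z >= config$z_floor)
}

#' Dice overlap of two binary masks
#' @param a,b logical volumes.
#' @return 2|A n B| / (|A| + |B|); 1 when both are empty.
#' @export
dice_coefficient <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}
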
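# Longitudinal four-class change masks: voxelwise combination of
# two-timepoint NAWM and WMH masks, small-cluster filtering, structural
# volumetrics and nearest-neighbour resampling onto the quantitative grid.

#' Derive the four longitudinal tissue classes
#'
#' Voxelwise set intersections of the two-timepoint masks:
#' stable NAWM = NAWM_bl & NAWM_fu; stable WMH = WMH_bl & WMH_fu;
#' progressing WMH = NAWM_bl & WMH_fu; regressing WMH = WMH_bl & NAWM_fu.
#' Voxels in neither intersection (e.g. WMH that became stroke) belong to
#' no class.
#'
#' @param nawm_bl,wmh_bl,nawm_fu,wmh_fu logical volumes on one grid; NAWM
#'   and WMH must be disjoint within each timepoint.
#' @return list of four logical volumes: \code{stable_nawm},
#'   \code{stable_wmh}, \code{progressing_wmh}, \code{regressing_wmh}.
#' @export
change_classes <- function(nawm_bl, wmh_bl, nawm_fu, wmh_fu) {
  d <- dim(nawm_bl)
  stopifnot(identical(d, dim(wmh_bl)), identical(d, dim(nawm_fu)),
            identical(d, dim(wmh_fu)))
  if (any(nawm_bl & wmh_bl) || any(nawm_fu & wmh_fu))
    stop("NAWM and WMH masks overlap within a timepoint")
  list(
    stable_nawm = nawm_bl & nawm_fu,
    stable_wmh = wmh_bl & wmh_fu,
    progressing_wmh = nawm_bl & wmh_fu,
    regressing_wmh = wmh_bl & nawm_fu
  )
}

#' Label connected components of a 3-D binary mask
#'
#' Vectorized flood fill: each component is grown from a seed voxel by
#' repeated one-voxel dilation restricted to the mask.
#'
#' @param mask logical 3-D array.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return integer array of component labels (0 outside the mask).
#' @export
label_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  off <- neighbour_offsets(as.integer(connectivity))
  # linear-index offsets on a grid padded by 1 to avoid wraparound
  dp <- d + 2L
  pad <- array(FALSE, dp)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  offs <- off[, 1] + off[, 2] * dp[1] + off[, 3] * dp[1] * dp[2]
  labels <- array(0L, dp)
  remaining <- which(pad)
  comp <- 0L
  while (length(remaining) > 0L) {
    comp <- comp + 1L
    frontier <- remaining[1L]
    labels[frontier] <- comp
    while (length(frontier) > 0L) {
      nb <- unique(as.vector(outer(frontier, offs, `+`)))
      nb <- nb[pad[nb] & labels[nb] == 0L]
      labels[nb] <- comp
      frontier <- nb
    }
    remaining <- remaining[labels[remaining] == 0L]
  }
  out <- labels[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)]
  array(out, d)
}

#' Remove connected components smaller than a voxel-count threshold
#'
#' Components with fewer than \code{min_size} voxels are dropped (the
#' default 5 keeps only clusters larger than half a 2 mm voxel when applied
#' on a 1 mm structural grid). Applied to each class mask before
#' resampling to the quantitative grid, never before structural-space
#' volumetrics.
#'
#' @param mask logical 3-D array.
#' @param min_size minimum component size in voxels (components with
#'   \code{< min_size} voxels are removed).
#' @param connectivity 6, 18 or 26.
#' @return filtered logical array.
#' @export
filter_small_clusters <- function(mask, min_size = 5L, connectivity = 26L) {
  if (min_size <= 1L) return(mask)
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) return(mask)
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_size)
  array(lab %in% keep, dim(mask))
}

#' Nearest-neighbour resampling between aligned grids
#'
#' Both grids must share the physical field of view (the phantoms are
#' generated pre-aligned, so no registration is estimated). Each target
#' voxel takes the value of the source voxel whose center is nearest its
#' own center; binary input yields binary output.
#'
#' @param vol source array (logical, integer or numeric).
#' @param src_voxel_mm source voxel dimensions, mm.
#' @param target_shape target grid dimensions.
#' @param target_voxel_mm target voxel dimensions, mm.
#' @return array on the target grid, same storage mode as the input.
#' @export
resample_nn <- function(vol, src_voxel_mm, target_shape, target_voxel_mm) {
  d <- dim(vol)
  ext_src <- d * src_voxel_mm
  ext_tgt <- target_shape * target_voxel_mm
  if (max(abs(ext_src - ext_tgt)) > 1e-6)
    stop("source and target grids must cover the same physical extent")
  idx <- lapply(1:3, function(a) {
    x <- (seq_len(target_shape[a]) - 0.5) * target_voxel_mm[a]
    clamp(floor(x / src_voxel_mm[a]) + 1L, 1L, d[a])
  })
  out <- vol[idx[[1]], idx[[2]], idx[[3]]]
  array(out, target_shape)
}

#' Structural-space class volumes in mL
#'
#' Volume = voxel count x voxel volume. Computed on the unfiltered masks
#' (the cluster-size threshold applies only before resampling into the
#' quantitative space, not to volumetrics).
#'
#' @param masks named list of logical volumes (e.g. from
#'   \code{change_classes}).
#' @param voxel_mm voxel dimensions, mm.
#' @return data frame with columns \code{class} and \code{volume_ml}.
#' @export
class_volumes <- function(masks, voxel_mm) {
  vv <- prod(voxel_mm) / 1000  # mm^3 -> mL
  data.frame(class = names(masks),
             volume_ml = vapply(masks, function(m) sum(m) * vv, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Derive NAWM by subtraction
#'
#' NAWM = WM minus WMH minus stroke. Warns (with a voxel count) if the WMH
#' mask extends outside the supplied WM mask.
#'
#' @param wm_mask,wmh_mask,stroke_mask logical volumes on one grid.
#' @return logical NAWM volume, disjoint from both subtracted masks.
#' @export
derive_nawm <- function(wm_mask, wmh_mask, stroke_mask) {
  stopifnot(identical(dim(wm_mask), dim(wmh_mask)),
            identical(dim(wm_mask), dim(stroke_mask)))
  outside <- sum(wmh_mask & !wm_mask)
  if (outside > 0)
    warning(sprintf("%d WMH voxels fall outside the WM mask", outside))
  wm_mask & !wmh_mask & !stroke_mask
}
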
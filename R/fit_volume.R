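# Apply per-voxel fitters over masked voxels of a 4-D series, producing
# quantitative parameter maps with per-voxel convergence flags.

#' Apply a per-voxel fitter over a mask
#'
#' Generic map-fitting plumbing: runs \code{fit_fn(signal_vector, ...)} at
#' every in-mask voxel and collects the named scalar outputs into 3-D
#' arrays. Outside-mask voxels hold NA; a \code{converged} logical array is
#' always returned (taken from the fitter's \code{converged} element, or
#' TRUE if absent).
#'
#' @param data 4-D array (x, y, z, volume).
#' @param mask logical 3-D array within the data grid.
#' @param fit_fn function of a per-voxel signal vector returning a named
#'   list.
#' @param params names of scalar outputs to collect.
#' @param ... further arguments passed to \code{fit_fn}.
#' @return list of 3-D arrays (one per requested parameter) plus
#'   \code{converged}.
#' @export
fit_volume <- function(data, mask, fit_fn, params, ...) {
  d <- dim(data)
  stopifnot(length(d) == 4L, identical(d[1:3], dim(mask)))
  idx <- which(mask)
  if (length(idx) == 0L) warning("empty mask; returning empty maps")
  nvol <- d[4]
  flat <- matrix(data, prod(d[1:3]), nvol)
  out <- setNames(lapply(params, function(p)
    array(NA_real_, d[1:3])), params)
  conv <- array(NA, d[1:3])
  for (v in idx) {
    f <- fit_fn(flat[v, ], ...)
    for (p in params) out[[p]][v] <- f[[p]]
    conv[v] <- isTRUE(f$converged %||% TRUE)
  }
  out$converged <- conv
  out
}

#' Fit FA/MD maps from a voxels-x-volumes signal matrix
#'
#' Signal rows correspond to \code{voxels} (linear indices into a grid of
#' dimension \code{grid_shape}); only rows whose voxel lies in \code{mask}
#' are fitted.
#'
#' @param signals voxels x volumes matrix.
#' @param voxels linear indices of the signal rows.
#' @param grid_shape 3-D grid dimensions.
#' @param mask logical array on that grid.
#' @param scheme a \code{dwi_scheme}.
#' @return list of arrays \code{fa}, \code{md} and \code{converged}.
#' @export
fit_dti_map <- function(signals, voxels, grid_shape, mask, scheme) {
  fa <- array(NA_real_, grid_shape)
  md <- array(NA_real_, grid_shape)
  conv <- array(NA, grid_shape)
  sel <- which(mask[voxels])
  for (i in sel) {
    f <- fit_dti_wls(signals[i, ], scheme)
    v <- voxels[i]
    fa[v] <- f$fa; md[v] <- f$md; conv[v] <- f$converged
  }
  list(fa = fa, md = md, converged = conv)
}

#' Fit a T1 map from a 4-D SPGR/IR-SPGR series
#'
#' Vectorized DESPOT1-HIFI over all in-mask voxels.
#'
#' @param data 4-D array, volumes ordered SPGR angles then IR.
#' @param mask logical 3-D array.
#' @param protocol a \code{qt1_protocol}.
#' @param b1_fixed optional 3-D array of known B1 (e.g. the baseline HIFI
#'   estimate, re-used for a sparse follow-up protocol).
#' @return list of arrays \code{t1}, \code{b1} and \code{converged}.
#' @export
fit_t1_map <- function(data, mask, protocol, b1_fixed = NULL) {
  d <- dim(data)
  idx <- which(mask)
  flat <- matrix(data, prod(d[1:3]), d[4])
  fit <- fit_despot1_hifi(flat[idx, , drop = FALSE], protocol,
                          b1_fixed = if (!is.null(b1_fixed))
                            b1_fixed[idx])
  t1 <- array(NA_real_, d[1:3]); b1 <- array(NA_real_, d[1:3])
  conv <- array(NA, d[1:3])
  t1[idx] <- fit$t1_s; b1[idx] <- fit$b1; conv[idx] <- fit$converged
  list(t1 = t1, b1 = b1, converged = conv)
}

#' Fit NODDI maps from a voxels-x-volumes signal matrix
#'
#' @inheritParams fit_dti_map
#' @param quad quadrature rule shared across voxels.
#' @return list of arrays \code{ndi}, \code{odi}, \code{fwf},
#'   \code{converged}.
#' @export
fit_noddi_map <- function(signals, voxels, grid_shape, mask, scheme,
                          quad = watson_quadrature()) {
  pre <- noddi_precompute(scheme, quad)
  ndi <- array(NA_real_, grid_shape)
  odi <- array(NA_real_, grid_shape)
  fwf <- array(NA_real_, grid_shape)
  conv <- array(NA, grid_shape)
  sel <- which(mask[voxels])
  for (i in sel) {
    f <- fit_noddi(signals[i, ], scheme, quad, pre)
    v <- voxels[i]
    ndi[v] <- f$v_ic; odi[v] <- f$odi; fwf[v] <- f$v_iso
    conv[v] <- f$converged
  }
  list(ndi = ndi, odi = odi, fwf = fwf, converged = conv)
}
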
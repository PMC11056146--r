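#' @importFrom stats coef cov integrate lm optim pf pt ptukey qt qtukey rnorm runif sd setNames t.test var
#' @importFrom utils read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a positive finite scalar", name), call. = FALSE)
}

#' Shift an array along one axis, zero-filling the vacated slab
#' @noRd
shift_array <- function(a, axis, by) {
  if (by == 0L) return(a)
  d <- dim(a)
  idx_src <- lapply(d, seq_len)
  idx_dst <- idx_src
  n <- d[axis]
  if (abs(by) >= n) return(array(0, dim = d))
  if (by > 0) {
    idx_dst[[axis]] <- (by + 1L):n
    idx_src[[axis]] <- 1L:(n - by)
  } else {
    idx_dst[[axis]] <- 1L:(n + by)
    idx_src[[axis]] <- (1L - by):n
  }
  out <- array(0, dim = d)
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

#' Neighbourhood offsets for 3-D connectivity
#' @noRd
neighbour_offsets <- function(connectivity = 26L) {
  stopifnot(connectivity %in% c(6L, 18L, 26L))
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  if (connectivity == 6L) off <- off[rowSums(abs(off)) == 1, , drop = FALSE]
  if (connectivity == 18L) off <- off[rowSums(abs(off)) <= 2, , drop = FALSE]
  off
}

#' Separable 3-D Gaussian smoothing
#'
#' Convolves a 3-D array with an isotropic Gaussian kernel (in voxel units)
#' using three 1-D passes with zero-padded borders. A sigma of 0 returns the
#' input unchanged.
#'
#' @param vol 3-D numeric array.
#' @param sigma_vox kernel standard deviation in voxels.
#' @return smoothed array of the same dimensions.
#' @export
gaussian_smooth3d <- function(vol, sigma_vox) {
  stopifnot(length(dim(vol)) == 3L, sigma_vox >= 0)
  if (sigma_vox == 0) return(vol)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  k <- k / sum(k)
  out <- vol
  for (axis in 1:3) {
    acc <- array(0, dim = dim(out))
    for (j in seq_along(k)) {
      acc <- acc + k[j] * shift_array(out, axis, j - r - 1L)
    }
    out <- acc
  }
  out
}
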
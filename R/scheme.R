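# Diffusion acquisition schemes (b-values + gradient directions)

#' Quasi-uniform unit directions on the sphere
#'
#' Deterministic spherical Fibonacci point set; used to build synthetic
#' gradient tables with good angular coverage.
#'
#' @param n number of directions.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  m <- cbind(r * cos(phi), r * sin(phi), z)
  m / sqrt(rowSums(m^2))
}

#' Construct a diffusion scheme
#'
#' Bundles per-volume b-values (s/mm^2) and unit gradient directions, labels
#' shells by rounded b-value, and records the single-shell subset
#' (b in {0, 1000}) used for tensor fitting. Directions of b>0 volumes must
#' be unit-norm; b=0 volumes may carry zero vectors.
#'
#' @param bvals numeric vector of b-values, s/mm^2.
#' @param bvecs n x 3 matrix of gradient directions.
#' @return object of class \code{dwi_scheme}.
#' @export
dwi_scheme <- function(bvals, bvecs) {
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) == 3L && ncol(bvecs) != 3L) bvecs <- t(bvecs)
  stopifnot(length(bvals) == nrow(bvecs), ncol(bvecs) == 3L)
  nz <- bvals > 0
  nrm <- sqrt(rowSums(bvecs^2))
  if (any(nz & abs(nrm - 1) > 1e-6))
    stop("gradient directions must be unit-norm for b > 0")
  subset <- which(bvals < 50 | abs(bvals - 1000) < 50)
  if (length(subset) < 7L)
    stop("single-shell subset has fewer than 7 volumes; tensor not identifiable")
  structure(list(
    bvals = as.numeric(bvals),
    bvecs = bvecs,
    shell_labels = round(bvals / 50) * 50,
    single_shell_subset = subset
  ), class = "dwi_scheme")
}

#' Baseline multishell scheme
#'
#' Five shells: b = 0 (15 volumes), 200 (3), 600 (6), 1000 (64), 2000 (64).
#' The two 64-direction shells use rotated copies of the same quasi-uniform
#' point set.
#'
#' @return a \code{dwi_scheme}.
#' @export
baseline_dwi_scheme <- function() {
  rot <- function(m, ang) {
    R <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
    m %*% t(R)
  }
  bvals <- c(rep(0, 15), rep(200, 3), rep(600, 6), rep(1000, 64), rep(2000, 64))
  bvecs <- rbind(
    matrix(0, 15, 3),
    fibonacci_directions(3),
    fibonacci_directions(6),
    fibonacci_directions(64),
    rot(fibonacci_directions(64), 0.35)
  )
  dwi_scheme(bvals, bvecs)
}

#' Follow-up single-shell scheme
#'
#' b = 0 (8 volumes) plus b = 1000 (64 directions); the subset of the
#' baseline acquisition re-acquired at the 1-year visit.
#'
#' @return a \code{dwi_scheme}.
#' @export
followup_dwi_scheme <- function() {
  bvals <- c(rep(0, 8), rep(1000, 64))
  bvecs <- rbind(matrix(0, 8, 3), fibonacci_directions(64))
  dwi_scheme(bvals, bvecs)
}

#' Restrict a scheme to its single-shell (b in {0, 1000}) subset
#' @param scheme a \code{dwi_scheme}.
#' @return a \code{dwi_scheme} containing only the subset volumes.
#' @export
single_shell_scheme <- function(scheme) {
  s <- scheme$single_shell_subset
  dwi_scheme(scheme$bvals[s], scheme$bvecs[s, , drop = FALSE])
}

#' Write FSL-dialect bvals/bvecs files
#'
#' One row of b-values; three rows of direction components.
#'
#' @param scheme a \code{dwi_scheme}.
#' @param prefix path prefix; writes \code{<prefix>.bval} and
#'   \code{<prefix>.bvec}.
#' @return invisibly, the two file paths.
#' @export
write_fsl_scheme <- function(scheme, prefix) {
  bval <- paste(format(scheme$bvals, trim = TRUE), collapse = " ")
  writeLines(bval, paste0(prefix, ".bval"))
  bv <- apply(t(scheme$bvecs), 1, function(r)
    paste(format(r, trim = TRUE, digits = 8), collapse = " "))
  writeLines(bv, paste0(prefix, ".bvec"))
  invisible(c(paste0(prefix, ".bval"), paste0(prefix, ".bvec")))
}

#' Read FSL-dialect bvals/bvecs files
#' @param prefix path prefix as in \code{write_fsl_scheme}.
#' @return a \code{dwi_scheme}.
#' @export
read_fsl_scheme <- function(prefix) {
  bvals <- scan(paste0(prefix, ".bval"), quiet = TRUE)
  bvecs <- matrix(scan(paste0(prefix, ".bvec"), quiet = TRUE),
                  nrow = 3, byrow = TRUE)
  dwi_scheme(bvals, t(bvecs))
}
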
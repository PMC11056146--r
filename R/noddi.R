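# Watson-NODDI forward model and fitting.
#
# Three compartments per voxel: intracellular Watson-dispersed sticks
# (volume fraction v_ic of the tissue), an extracellular tensor whose
# diffusivities are tortuosity-coupled to v_ic, and isotropic free water
# (fraction v_iso of the voxel). Intrinsic diffusivities are fixed at the
# in-vivo white-matter defaults.

NODDI_D_PAR <- 1.7e-3   # intrinsic parallel diffusivity, mm^2/s
NODDI_D_ISO <- 3.0e-3   # free-water diffusivity, mm^2/s

#' Dawson function
#'
#' F(x) = exp(-x^2) * integral_0^x exp(t^2) dt. Substituting u = x - t gives
#' F(x) = integral_0^x exp(u^2 - 2xu) du, whose integrand is bounded by 1
#' and decays like exp(-2xu); it is evaluated by fixed Gauss-Legendre
#' quadrature on [0, u_max], where u_max truncates the exponent at -45
#' (double-precision negligible). Accurate to ~1e-13 for all x >= 0,
#' including large arguments where the erfi route overflows.
#'
#' @param x numeric vector, x >= 0.
#' @return F(x).
#' @export
dawson_f <- function(x) {
  gl <- pracma::gaussLegendre(60, 0, 1)
  vapply(x, function(xi) {
    if (xi == 0) return(0)
    umax <- if (xi^2 > 45) xi - sqrt(xi^2 - 45) else xi
    u <- gl$x * umax
    sum(gl$w * exp(u^2 - 2 * xi * u)) * umax
  }, numeric(1))
}

#' Watson second moment about the mean axis
#'
#' Returns tau1 = E[(n . mu)^2] under the Watson density with concentration
#' kappa, via the Dawson-function closed form
#' tau1 = 1/(2 sqrt(kappa) F(sqrt(kappa))) - 1/(2 kappa), with the series
#' limit 1/3 + 4 kappa/45 for small kappa. tau1(0) = 1/3 (uniform) and
#' tau1 -> 1 as kappa -> Inf (delta at mu).
#'
#' @param kappa numeric vector, >= 0.
#' @return tau1 in [1/3, 1].
#' @export
watson_tau1 <- function(kappa) {
  stopifnot(all(kappa >= 0))
  out <- numeric(length(kappa))
  tiny <- kappa < 1e-4
  out[tiny] <- 1 / 3 + 4 * kappa[tiny] / 45
  if (any(!tiny)) {
    k <- kappa[!tiny]
    s <- sqrt(k)
    out[!tiny] <- 1 / (2 * s * dawson_f(s)) - 1 / (2 * k)
  }
  clamp(out, 1 / 3, 1)
}

#' Orientation dispersion index from Watson concentration
#' @param kappa concentration, >= 0.
#' @return ODI = (2/pi) * atan(1/kappa), in (0, 1].
#' @export
odi_from_kappa <- function(kappa) (2 / pi) * atan2(1, kappa)

#' Watson concentration from orientation dispersion index
#' @param odi ODI in (0, 1].
#' @return kappa >= 0.
#' @export
kappa_from_odi <- function(odi) {
  stopifnot(all(odi > 0), all(odi <= 1))
  1 / tan(pi / 2 * odi)
}

#' Spherical quadrature rule for Watson integrals
#'
#' Product rule: Gauss-Legendre in t = cos(theta) on [0, 1] times a uniform
#' grid in azimuth, doubled for antipodal symmetry (all integrands here are
#' even under n -> -n). Weights sum to 4*pi.
#'
#' @param n_t Gauss-Legendre points in cos(theta).
#' @param n_phi azimuthal points.
#' @return list with unit \code{nodes} (m x 3) and \code{w} (length m).
#' @export
watson_quadrature <- function(n_t = 60, n_phi = 48) {
  gl <- pracma::gaussLegendre(n_t, 0, 1)
  phi <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  t <- rep(gl$x, each = n_phi)
  w <- rep(gl$w, each = n_phi) * (2 * pi / n_phi) * 2
  s <- sqrt(pmax(0, 1 - t^2))
  ph <- rep(phi, times = n_t)
  list(nodes = cbind(s * cos(ph), s * sin(ph), t), w = w)
}

# Per-scheme precomputation: stick attenuation at every (volume, node) pair.
# d_par is a fixed constant so this matrix is reused across all model
# evaluations on a given scheme.
noddi_precompute <- function(scheme, quad) {
  E <- (scheme$bvecs %*% t(quad$nodes))^2
  list(quad = quad, M_stick = exp(-(scheme$bvals * NODDI_D_PAR) * E))
}

noddi_forward_pre <- function(v_ic, v_iso, kappa, mu, scheme, pre) {
  quad <- pre$quad
  u <- quad$w * exp(kappa * as.vector(quad$nodes %*% mu)^2)
  A_ic <- as.vector(pre$M_stick %*% u) / sum(u)
  tau1 <- watson_tau1(kappa)
  d_perp <- NODDI_D_PAR * (1 - v_ic)
  d_ax <- d_perp + (NODDI_D_PAR - d_perp) * tau1
  d_rad <- d_perp + (NODDI_D_PAR - d_perp) * (1 - tau1) / 2
  cos2 <- as.vector(scheme$bvecs %*% mu)^2
  A_ec <- exp(-scheme$bvals * (d_rad + (d_ax - d_rad) * cos2))
  A_iso <- exp(-scheme$bvals * NODDI_D_ISO)
  (1 - v_iso) * (v_ic * A_ic + (1 - v_ic) * A_ec) + v_iso * A_iso
}

#' Watson-NODDI forward model
#'
#' Normalized signal S/S0 for every volume of a diffusion scheme. The
#' intracellular term integrates the stick response over the Watson
#' orientation density by spherical quadrature; the extracellular tensor has
#' axial/radial diffusivities set by the tortuosity constraint
#' d_perp = d_par (1 - v_ic) and the Watson moment tau1.
#'
#' @param v_ic intracellular (neurite) volume fraction of the tissue, [0,1].
#' @param v_iso free-water volume fraction of the voxel, [0,1].
#' @param kappa Watson concentration, >= 0.
#' @param mu unit 3-vector, mean neurite orientation.
#' @param scheme a \code{dwi_scheme}.
#' @param quad optional quadrature rule from \code{watson_quadrature}.
#' @return numeric vector of normalized signals, one per volume.
#' @export
noddi_forward <- function(v_ic, v_iso, kappa, mu, scheme,
                          quad = watson_quadrature()) {
  stopifnot(v_ic >= 0, v_ic <= 1, v_iso >= 0, v_iso <= 1, kappa >= 0)
  mu <- mu / sqrt(sum(mu^2))
  pre <- noddi_precompute(scheme, quad)
  noddi_forward_pre(v_ic, v_iso, kappa, mu, scheme, pre)
}

# Block-vectorized forward model: one voxel per column. Used by the phantom
# generator, where every voxel has its own parameters.
noddi_forward_block <- function(v_ic, v_iso, kappa, mu, scheme, pre) {
  nvox <- length(v_ic)
  stopifnot(ncol(mu) == nvox)
  quad <- pre$quad
  C2 <- (quad$nodes %*% mu)^2                      # nnode x nvox
  U <- quad$w * exp(sweep(C2, 2, kappa, `*`))
  A_ic <- sweep(pre$M_stick %*% U, 2, colSums(U), `/`)  # nvol x nvox
  tau1 <- watson_tau1(kappa)
  d_perp <- NODDI_D_PAR * (1 - v_ic)
  d_ax <- d_perp + (NODDI_D_PAR - d_perp) * tau1
  d_rad <- d_perp + (NODDI_D_PAR - d_perp) * (1 - tau1) / 2
  g2 <- (scheme$bvecs %*% mu)^2                    # nvol x nvox
  A_ec <- exp(-scheme$bvals *
                (sweep(g2, 2, d_ax - d_rad, `*`) +
                   matrix(d_rad, nrow(g2), nvox, byrow = TRUE)))
  A_iso <- exp(-scheme$bvals * NODDI_D_ISO)
  sweep(v_ic * t(A_ic) + (1 - v_ic) * t(A_ec), 1, 1 - v_iso, `*`) +
    outer(v_iso, A_iso)
  # returns nvox x nvol; transpose for volume-major layout
}

#' Fit the Watson-NODDI model to one voxel
#'
#' Normalizes by the mean b=0 signal, seeds the mean orientation from the
#' single-shell tensor's principal eigenvector, coarse-grids
#' (v_ic, ODI, v_iso), then runs bounded quasi-Newton least squares over all
#' five parameters (v_ic, v_iso, ODI, and the two orientation angles).
#' Requires a multishell scheme (b=0 plus at least two nonzero shells).
#'
#' @param signals numeric vector, one raw signal per scheme volume.
#' @param scheme a multishell \code{dwi_scheme}.
#' @param quad quadrature rule; shared across voxels for speed.
#' @param pre optional precomputation from \code{noddi_precompute}.
#' @param odi_bounds lower/upper ODI bounds for the optimizer.
#' @return list with \code{v_ic} (NDI), \code{v_iso} (FWF), \code{odi},
#'   \code{kappa}, \code{mu}, \code{rss}, \code{converged}.
#' @export
fit_noddi <- function(signals, scheme, quad = watson_quadrature(),
                      pre = NULL, odi_bounds = c(0.02, 1)) {
  shells <- unique(scheme$shell_labels)
  if (length(setdiff(shells, 0)) < 2L)
    stop("NODDI requires b=0 plus at least two nonzero shells")
  if (is.null(pre)) pre <- noddi_precompute(scheme, quad)
  b0 <- scheme$bvals < 50
  S0 <- mean(signals[b0])
  if (!is.finite(S0) || S0 <= 0)
    return(list(v_ic = NA_real_, v_iso = NA_real_, odi = NA_real_,
                kappa = NA_real_, mu = c(NA, NA, NA), rss = NA_real_,
                converged = FALSE))
  A_obs <- signals / S0

  # orientation seed from the single-shell tensor
  e1 <- tryCatch(fit_dti_wls(signals, scheme)$evec[, 1],
                 error = function(e) c(0, 0, 1))
  th0 <- acos(clamp(e1[3], -1, 1))
  ph0 <- atan2(e1[2], e1[1])

  obj <- function(p) {
    mu <- c(sin(p[4]) * cos(p[5]), sin(p[4]) * sin(p[5]), cos(p[4]))
    A <- noddi_forward_pre(p[1], p[2], kappa_from_odi(clamp(p[3], 1e-4, 1)),
                           mu, scheme, pre)
    sum((A - A_obs)^2)
  }

  grid <- expand.grid(v_ic = c(0.2, 0.4, 0.6, 0.8),
                      v_iso = c(0.02, 0.1, 0.25, 0.6),
                      odi = c(0.05, 0.15, 0.3, 0.6))
  gv <- apply(grid, 1, function(g) obj(c(g[1], g[2], g[3], th0, ph0)))
  p0 <- as.numeric(grid[which.min(gv), ])
  fit <- optim(c(p0, th0, ph0), obj, method = "L-BFGS-B",
               lower = c(0, 0, odi_bounds[1], th0 - pi / 2, ph0 - pi / 2),
               upper = c(1, 1, odi_bounds[2], th0 + pi / 2, ph0 + pi / 2),
               control = list(maxit = 300, factr = 1e4))
  p <- fit$par
  mu <- c(sin(p[4]) * cos(p[5]), sin(p[4]) * sin(p[5]), cos(p[4]))
  list(v_ic = p[1], v_iso = p[2], odi = p[3],
       kappa = kappa_from_odi(clamp(p[3], 1e-4, 1)),
       mu = mu, rss = fit$value, converged = fit$convergence == 0)
}
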
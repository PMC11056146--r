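# Diffusion tensor fitting by iterated weighted least squares on the
# log-linearized signal model ln S = ln S0 - b g' D g.
#
# Only the single-shell subset (b in {0, 1000} s/mm^2) of a scheme is used,
# so that tensor metrics are comparable between a multishell baseline and a
# single-shell follow-up acquisition.

# design matrix rows: [1, -b gx^2, -b gy^2, -b gz^2, -2b gxgy, -2b gxgz, -2b gygz]
dti_design <- function(scheme) {
  s <- scheme$single_shell_subset
  b <- scheme$bvals[s]
  g <- scheme$bvecs[s, , drop = FALSE]
  cbind(1,
        -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
        -2 * b * g[, 1] * g[, 2],
        -2 * b * g[, 1] * g[, 3],
        -2 * b * g[, 2] * g[, 3])
}

tensor_from_beta <- function(beta) {
  matrix(c(beta[2], beta[5], beta[6],
           beta[5], beta[3], beta[7],
           beta[6], beta[7], beta[4]), 3, 3)
}

#' Fractional anisotropy from tensor eigenvalues
#' @param ev numeric vector of 3 eigenvalues.
#' @return FA in [0, 1].
#' @export
fa_from_eigenvalues <- function(ev) {
  num <- (ev[1] - ev[2])^2 + (ev[2] - ev[3])^2 + (ev[3] - ev[1])^2
  den <- sum(ev^2)
  if (den <= 0) return(0)
  clamp(sqrt(0.5 * num / den), 0, 1)
}

#' Fit a diffusion tensor to one voxel (iterated WLS)
#'
#' Solves the log-linear system by ordinary least squares, then re-solves
#' with weights equal to the squared predicted signals, iterating
#' \code{n_iter} times or until the coefficient change falls below
#' \code{tol}. Nonpositive signals are replaced by the smallest positive
#' signal in the voxel before the log transform. Eigenvalues are clamped at
#' 1e-12 so FA stays within [0, 1] for noisy voxels.
#'
#' @param signals numeric vector, one raw signal per scheme volume.
#' @param scheme a \code{dwi_scheme}; only its single-shell subset is used.
#' @param n_iter number of reweighting iterations (default 2).
#' @param tol convergence tolerance on the coefficient vector.
#' @return list with \code{log_s0}, \code{tensor} (mm^2/s), \code{evals},
#'   \code{evec}, \code{fa}, \code{md}, \code{converged}.
#' @export
fit_dti_wls <- function(signals, scheme, n_iter = 2L, tol = 1e-6) {
  X <- dti_design(scheme)
  S <- signals[scheme$single_shell_subset]
  if (!any(S > 0))
    return(list(log_s0 = NA_real_, tensor = matrix(NA_real_, 3, 3),
                evals = rep(NA_real_, 3), evec = matrix(NA_real_, 3, 3),
                fa = NA_real_, md = NA_real_, converged = FALSE))
  S[S <= 0] <- min(S[S > 0])
  y <- log(S)
  XtX <- crossprod(X)
  ok <- TRUE
  beta <- tryCatch(solve(XtX, crossprod(X, y)),
                   error = function(e) { ok <<- FALSE; NULL })
  if (!ok)
    return(list(log_s0 = NA_real_, tensor = matrix(NA_real_, 3, 3),
                evals = rep(NA_real_, 3), evec = matrix(NA_real_, 3, 3),
                fa = NA_real_, md = NA_real_, converged = FALSE))
  for (it in seq_len(n_iter)) {
    w <- exp(X %*% beta)^2          # predicted-signal-squared weights
    Xw <- X * as.vector(w)
    beta_new <- tryCatch(solve(crossprod(X, Xw), crossprod(Xw, y)),
                         error = function(e) { ok <<- FALSE; beta })
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (!ok || delta < tol) break
  }
  D <- tensor_from_beta(beta)
  ed <- eigen(D, symmetric = TRUE)
  ev <- pmax(ed$values, 1e-12)
  list(log_s0 = beta[1], tensor = D, evals = ev, evec = ed$vectors,
       fa = fa_from_eigenvalues(ev), md = mean(ev), converged = ok)
}

#' Tensor-equivalent FA/MD of a Watson-NODDI parameter set
#'
#' Evaluates the noise-free NODDI signal on a scheme's single-shell subset
#' and fits the tensor to it. This deterministic map defines the ground
#' truth FA/MD of a phantom tissue class (the generative model for
#' diffusion signals is NODDI, so tensor metrics are derived quantities).
#'
#' @param v_ic,v_iso,odi NODDI parameters.
#' @param scheme a \code{dwi_scheme} (defaults to the baseline scheme).
#' @param quad quadrature rule.
#' @return list with \code{fa} and \code{md} (mm^2/s).
#' @export
noddi_tensor_metrics <- function(v_ic, v_iso, odi,
                                 scheme = baseline_dwi_scheme(),
                                 quad = watson_quadrature()) {
  A <- noddi_forward(v_ic, v_iso, kappa_from_odi(odi), c(0, 0, 1),
                     scheme, quad)
  f <- fit_dti_wls(A, scheme)
  list(fa = f$fa, md = f$md)
}
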
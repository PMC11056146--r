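# Small in-code fixtures shared across tests.

# noise-free diffusion signals from an explicit tensor (mm^2/s)
tensor_signals <- function(scheme, evals, R = diag(3), s0 = 1) {
  D <- R %*% diag(evals) %*% t(R)
  s0 * exp(-scheme$bvals * rowSums((scheme$bvecs %*% D) * scheme$bvecs))
}

# random rotation matrix
random_rotation <- function() {
  qr.Q(qr(matrix(rnorm(9), 3)))
}

# noise-free SPGR + IR-SPGR signal vector for one voxel
qt1_signals <- function(protocol, t1_ms, b1 = 1, m0 = 1000) {
  c(vapply(protocol$spgr_flip_deg, function(a)
    spgr_signal(m0, t1_ms, b1, a, protocol$tr_ms), numeric(1)),
    vapply(protocol$ir_ti_ms, function(ti)
      ir_spgr_signal(m0, t1_ms, b1, protocol$ir_flip_deg, ti), numeric(1)))
}

# small phantom spec for fast tests (any argument may be overridden)
small_phantom_spec <- function(...) {
  args <- list(grid_shape_structural = c(32L, 32L, 32L),
               grid_shape_diffusion = c(16L, 16L, 16L),
               n_lesions = 8L, n_de_novo = 1L,
               lesion_radius_range_mm = c(2, 4))
  do.call(phantom_spec, utils::modifyList(args, list(...)))
}

# brute-force per-voxel four-class oracle
change_classes_oracle <- function(nawm_bl, wmh_bl, nawm_fu, wmh_fu) {
  d <- dim(nawm_bl)
  out <- list(stable_nawm = array(FALSE, d), stable_wmh = array(FALSE, d),
              progressing_wmh = array(FALSE, d),
              regressing_wmh = array(FALSE, d))
  for (v in seq_len(prod(d))) {
    if (nawm_bl[v] && nawm_fu[v]) out$stable_nawm[v] <- TRUE
    if (wmh_bl[v] && wmh_fu[v]) out$stable_wmh[v] <- TRUE
    if (nawm_bl[v] && wmh_fu[v]) out$progressing_wmh[v] <- TRUE
    if (wmh_bl[v] && nawm_fu[v]) out$regressing_wmh[v] <- TRUE
  }
  out
}

# queue-based flood-fill oracle for connected components
label_components_oracle <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  off <- wmhtraj:::neighbour_offsets(connectivity)
  lab <- array(0L, d)
  comp <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    comp <- comp + 1L
    queue <- start
    lab[start] <- comp
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      ijk <- arrayInd(v, d)
      for (r in seq_len(nrow(off))) {
        n <- ijk + off[r, ]
        if (any(n < 1L) || any(n > d)) next
        w <- n[1] + (n[2] - 1L) * d[1] + (n[3] - 1L) * d[1] * d[2]
        if (mask[w] && lab[w] == 0L) {
          lab[w] <- comp
          queue <- c(queue, w)
        }
      }
    }
  }
  lab
}

# data whose sample covariance is exactly compound-symmetric: whiten an
# arbitrary draw, then impose a CS covariance factor
make_cs_data <- function(n, k, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * k), n)
  Xc <- scale(X, scale = FALSE)
  W <- solve(chol(cov(Xc)))
  C <- 0.5 * diag(k) + 0.5  # CS: var 1, cov 0.5
  Xc %*% W %*% chol(C)
}

# random sparse logical volume
random_mask <- function(d, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(runif(prod(d)) < p, d)
}
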
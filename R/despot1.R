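# DESPOT1-HIFI T1 mapping: variable-flip-angle SPGR jointly fit with an
# inversion-recovery prepared acquisition to estimate the B1 flip-angle
# scale alongside T1 and M0.
#
# All protocol times are in milliseconds internally; fitted T1 is reported
# in seconds.

#' Quantitative T1 protocol descriptor
#'
#' @param spgr_flip_deg nominal SPGR flip angles, degrees, in (0, 90].
#' @param ir_ti_ms inversion times of the IR-prepared volumes, ms.
#' @param tr_ms SPGR repetition time, ms.
#' @param ir_flip_deg readout flip angle of the IR-prepared volumes.
#' @return object of class \code{qt1_protocol}.
#' @export
qt1_protocol <- function(spgr_flip_deg, ir_ti_ms, tr_ms = 10,
                         ir_flip_deg = 5) {
  stopifnot(length(spgr_flip_deg) >= 1, all(spgr_flip_deg > 0),
            all(spgr_flip_deg <= 90), all(ir_ti_ms > 0), tr_ms > 0,
            ir_flip_deg > 0, ir_flip_deg <= 90)
  structure(list(spgr_flip_deg = spgr_flip_deg, ir_ti_ms = ir_ti_ms,
                 tr_ms = tr_ms, ir_flip_deg = ir_flip_deg),
            class = "qt1_protocol")
}

#' Baseline QT1 protocol: SPGR at 2/5/12 degrees, IR at TI = 600 and 1500 ms
#' @param tr_ms SPGR repetition time, ms.
#' @return a \code{qt1_protocol}.
#' @export
baseline_qt1_protocol <- function(tr_ms = 10)
  qt1_protocol(c(2, 5, 12), c(600, 1500), tr_ms)

#' Follow-up QT1 protocol: SPGR at 2/12 degrees, IR at TI = 600 ms
#' @param tr_ms SPGR repetition time, ms.
#' @return a \code{qt1_protocol}.
#' @export
followup_qt1_protocol <- function(tr_ms = 10)
  qt1_protocol(c(2, 12), 600, tr_ms)

#' SPGR steady-state signal
#'
#' S = M0 sin(B1 a) (1 - E1) / (1 - E1 cos(B1 a)), E1 = exp(-TR/T1).
#' Vectorized over voxels (m0, t1_ms, b1 may be vectors).
#'
#' @param m0 equilibrium magnetization (arbitrary units).
#' @param t1_ms longitudinal relaxation time, ms.
#' @param b1 flip-angle scale.
#' @param alpha_deg nominal flip angle, degrees.
#' @param tr_ms repetition time, ms.
#' @return signal, same length as the voxel inputs.
#' @export
spgr_signal <- function(m0, t1_ms, b1, alpha_deg, tr_ms) {
  a <- b1 * alpha_deg * pi / 180
  E <- exp(-tr_ms / t1_ms)
  m0 * sin(a) * (1 - E) / (1 - E * cos(a))
}

#' IR-SPGR magnitude signal (ideal inversion)
#'
#' S = | M0 sin(B1 a) (1 - 2 exp(-TI/T1)) |. The magnitude nulls at
#' TI = T1 ln 2.
#'
#' @inheritParams spgr_signal
#' @param ti_ms inversion time, ms.
#' @return magnitude signal.
#' @export
ir_spgr_signal <- function(m0, t1_ms, b1, alpha_deg, ti_ms) {
  a <- b1 * alpha_deg * pi / 180
  abs(m0 * sin(a) * (1 - 2 * exp(-ti_ms / t1_ms)))
}

#' Linear DESPOT1 solution at fixed B1
#'
#' Regression of y = S/sin(B1 a) on x = S/tan(B1 a) over the SPGR angles;
#' the slope is E1 = exp(-TR/T1) and the intercept M0 (1 - E1). Vectorized:
#' \code{spgr} is a voxels x angles matrix.
#'
#' @param spgr matrix of SPGR signals, voxels x angles.
#' @param protocol a \code{qt1_protocol}.
#' @param b1 flip-angle scale, scalar or one value per voxel.
#' @return list with \code{t1_ms}, \code{m0}, \code{e1} vectors.
#' @export
despot1_linear <- function(spgr, protocol, b1 = 1) {
  spgr <- rbind(spgr)  # 1-voxel vectors become 1 x n matrices
  dimnames(spgr) <- NULL
  a <- outer(b1 * pi / 180, protocol$spgr_flip_deg)  # voxels x angles
  if (nrow(a) == 1L && nrow(spgr) > 1L)
    a <- matrix(a, nrow(spgr), ncol(a), byrow = TRUE)
  y <- spgr / sin(a)
  x <- spgr / tan(a)
  mx <- rowMeans(x); my <- rowMeans(y)
  sxx <- rowMeans(x^2) - mx^2
  sxy <- rowMeans(x * y) - mx * my
  e1 <- sxy / sxx
  e1[!is.finite(e1)] <- NA_real_
  e1c <- clamp(e1, 1e-6, 1 - 1e-9)
  t1 <- -protocol$tr_ms / log(e1c)
  m0 <- (my - e1c * mx) / (1 - e1c)
  list(t1_ms = t1, m0 = m0, e1 = e1)
}

# residual sum of squares of the joint forward model, vectorized
despot1_rss <- function(spgr, ir, protocol, t1_ms, m0, b1) {
  r <- 0
  for (j in seq_along(protocol$spgr_flip_deg)) {
    r <- r + (spgr_signal(m0, t1_ms, b1, protocol$spgr_flip_deg[j],
                          protocol$tr_ms) - spgr[, j])^2
  }
  for (j in seq_along(protocol$ir_ti_ms)) {
    r <- r + (ir_spgr_signal(m0, t1_ms, b1, protocol$ir_flip_deg,
                             protocol$ir_ti_ms[j]) - ir[, j])^2
  }
  r
}

# profile objective: linear DESPOT1 at the trial B1, full-model residual
despot1_profile_rss <- function(spgr, ir, protocol, b1) {
  lin <- despot1_linear(spgr, protocol, b1)
  t1 <- clamp(lin$t1_ms, 1, 2e4)
  m0 <- pmax(lin$m0, 0)
  list(rss = despot1_rss(spgr, ir, protocol, t1, m0, b1),
       t1_ms = t1, m0 = m0)
}

#' Joint DESPOT1-HIFI fit of T1, M0 and B1
#'
#' Minimizes the summed squared residual of the SPGR and IR-SPGR forward
#' models over (T1, M0, B1). Initialization is the linear DESPOT1 solution
#' at B1 = 1; B1 is then profiled over a coarse grid on [0.5, 1.5] with the
#' inner (T1, M0) solved linearly, refined by golden-section search, and the
#' triple is polished by damped Gauss-Newton steps on the full model. The
#' whole fit is vectorized over voxels.
#'
#' @param signals numeric vector (one voxel) or voxels x volumes matrix;
#'   columns ordered SPGR angles then IR volumes, matching the protocol.
#' @param protocol a \code{qt1_protocol}; needs >= 2 SPGR angles and >= 1
#'   IR volume.
#' @param b1_bounds allowed B1 range.
#' @param gn_iter Gauss-Newton polish iterations.
#' @param b1_fixed optional known B1 (scalar or per voxel). When given,
#'   B1 is not estimated: the fit reduces to (T1, M0). With few volumes
#'   (e.g. a 2-angle + 1-IR follow-up protocol) the joint three-parameter
#'   problem admits a second exact solution on the other branch of the IR
#'   magnitude null, so re-using a B1 map estimated from a richer
#'   acquisition is the well-posed option.
#' @return list of vectors \code{t1_s}, \code{m0}, \code{b1},
#'   \code{residual}, \code{converged}.
#' @export
fit_despot1_hifi <- function(signals, protocol, b1_bounds = c(0.5, 1.5),
                             gn_iter = 12L, b1_fixed = NULL) {
  if (length(protocol$spgr_flip_deg) < 2L || length(protocol$ir_ti_ms) < 1L)
    stop("DESPOT1-HIFI needs >= 2 SPGR angles and >= 1 IR volume")
  X <- rbind(signals)
  dimnames(X) <- NULL
  ns <- length(protocol$spgr_flip_deg)
  ni <- length(protocol$ir_ti_ms)
  stopifnot(ncol(X) == ns + ni)
  spgr <- X[, seq_len(ns), drop = FALSE]
  ir <- X[, ns + seq_len(ni), drop = FALSE]
  nvox <- nrow(X)
  dead <- rowSums(abs(X)) == 0

  estimate_b1 <- is.null(b1_fixed)
  if (estimate_b1) {
    # coarse B1 grid with profiled (T1, M0)
    b1_grid <- seq(b1_bounds[1], b1_bounds[2], by = 0.05)
    best_rss <- rep(Inf, nvox)
    best_b1 <- rep(1, nvox)
    for (b1 in b1_grid) {
      pr <- despot1_profile_rss(spgr, ir, protocol, rep(b1, nvox))
      upd <- is.finite(pr$rss) & pr$rss < best_rss
      best_rss[upd] <- pr$rss[upd]
      best_b1[upd] <- b1
    }
    # golden-section refinement within one grid step either side
    lo <- pmax(b1_bounds[1], best_b1 - 0.05)
    hi <- pmin(b1_bounds[2], best_b1 + 0.05)
    gr <- (sqrt(5) - 1) / 2
    c1 <- hi - gr * (hi - lo); c2 <- lo + gr * (hi - lo)
    f1 <- despot1_profile_rss(spgr, ir, protocol, c1)$rss
    f2 <- despot1_profile_rss(spgr, ir, protocol, c2)$rss
    for (it in 1:40) {
      left <- f1 < f2
      hi[left] <- c2[left]
      lo[!left] <- c1[!left]
      c1 <- hi - gr * (hi - lo); c2 <- lo + gr * (hi - lo)
      f1 <- despot1_profile_rss(spgr, ir, protocol, c1)$rss
      f2 <- despot1_profile_rss(spgr, ir, protocol, c2)$rss
    }
    b1 <- (lo + hi) / 2
  } else {
    b1 <- rep_len(b1_fixed, nvox)
  }
  pr <- despot1_profile_rss(spgr, ir, protocol, b1)
  t1 <- pr$t1_ms; m0 <- pr$m0
  rss <- pr$rss

  # damped Gauss-Newton polish of the joint objective
  alpha_s <- protocol$spgr_flip_deg * pi / 180
  alpha_i <- protocol$ir_flip_deg * pi / 180
  for (it in seq_len(gn_iter)) {
    J11 <- J12 <- J13 <- J22 <- J23 <- J33 <- rep(0, nvox)
    g1 <- g2 <- g3 <- rep(0, nvox)
    for (j in seq_len(ns)) {
      a <- b1 * alpha_s[j]
      E <- exp(-protocol$tr_ms / t1)
      den <- 1 - E * cos(a)
      S <- m0 * sin(a) * (1 - E) / den
      r <- S - spgr[, j]
      dS_dE <- m0 * sin(a) * (cos(a) - 1) / den^2
      dS_dT1 <- dS_dE * E * protocol$tr_ms / t1^2
      dS_dM0 <- S / pmax(m0, 1e-12)
      dS_dB1 <- alpha_s[j] * m0 * (1 - E) * (cos(a) - E) / den^2
      g1 <- g1 + r * dS_dT1; g2 <- g2 + r * dS_dM0; g3 <- g3 + r * dS_dB1
      J11 <- J11 + dS_dT1^2; J12 <- J12 + dS_dT1 * dS_dM0
      J13 <- J13 + dS_dT1 * dS_dB1; J22 <- J22 + dS_dM0^2
      J23 <- J23 + dS_dM0 * dS_dB1; J33 <- J33 + dS_dB1^2
    }
    for (j in seq_len(ni)) {
      ti <- protocol$ir_ti_ms[j]
      a <- b1 * alpha_i
      e <- exp(-ti / t1)
      gmod <- m0 * sin(a) * (1 - 2 * e)
      sgn <- sign(gmod); sgn[sgn == 0] <- 1
      r <- abs(gmod) - ir[, j]
      dS_dT1 <- sgn * m0 * sin(a) * (-2 * e * ti / t1^2)
      dS_dM0 <- sgn * sin(a) * (1 - 2 * e)
      dS_dB1 <- sgn * alpha_i * m0 * cos(a) * (1 - 2 * e)
      g1 <- g1 + r * dS_dT1; g2 <- g2 + r * dS_dM0; g3 <- g3 + r * dS_dB1
      J11 <- J11 + dS_dT1^2; J12 <- J12 + dS_dT1 * dS_dM0
      J13 <- J13 + dS_dT1 * dS_dB1; J22 <- J22 + dS_dM0^2
      J23 <- J23 + dS_dM0 * dS_dB1; J33 <- J33 + dS_dB1^2
    }
    lam <- 1e-9
    J11 <- J11 + lam; J22 <- J22 + lam; J33 <- J33 + lam
    if (estimate_b1) {
      # closed-form 3x3 solve per voxel (symmetric system)
      det <- J11 * (J22 * J33 - J23^2) - J12 * (J12 * J33 - J23 * J13) +
        J13 * (J12 * J23 - J22 * J13)
      det[abs(det) < 1e-300] <- NA_real_
      d1 <- (g1 * (J22 * J33 - J23^2) - g2 * (J12 * J33 - J13 * J23) +
               g3 * (J12 * J23 - J13 * J22)) / det
      d2 <- (-g1 * (J12 * J33 - J23 * J13) + g2 * (J11 * J33 - J13^2) -
               g3 * (J11 * J23 - J12 * J13)) / det
      d3 <- (g1 * (J12 * J23 - J22 * J13) - g2 * (J11 * J23 - J12 * J13) +
               g3 * (J11 * J22 - J12^2)) / det
    } else {
      det <- J11 * J22 - J12^2
      det[abs(det) < 1e-300] <- NA_real_
      d1 <- (g1 * J22 - g2 * J12) / det
      d2 <- (g2 * J11 - g1 * J12) / det
      d3 <- rep(0, nvox)
    }
    step <- rep(1, nvox)
    for (h in 1:6) {
      t1_new <- clamp(t1 - step * d1, 1, 2e4)
      m0_new <- pmax(m0 - step * d2, 1e-9)
      b1_new <- clamp(b1 - step * d3, b1_bounds[1], b1_bounds[2])
      rss_new <- despot1_rss(spgr, ir, protocol, t1_new, m0_new, b1_new)
      worse <- is.na(rss_new) | rss_new > rss
      if (!any(worse)) break
      step[worse] <- step[worse] / 2
    }
    ok <- !is.na(rss_new) & rss_new <= rss
    t1[ok] <- t1_new[ok]; m0[ok] <- m0_new[ok]; b1[ok] <- b1_new[ok]
    rss[ok] <- rss_new[ok]
  }

  conv <- !dead & is.finite(rss) & t1 > 1 & t1 < 2e4
  t1[dead] <- NA_real_; m0[dead] <- NA_real_; b1[dead] <- NA_real_
  list(t1_s = t1 / 1000, m0 = m0, b1 = b1, residual = rss,
       converged = conv)
}
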
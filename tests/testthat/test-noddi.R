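# Watson-NODDI forward model and fit

test_that("watson_tau1 matches the 1-D quadrature oracle and its limits", {
  expect_equal(watson_tau1(0), 1 / 3)
  expect_equal(watson_tau1(1e7), 1, tolerance = 1e-3)
  # oracle: tau1 = int t^2 e^{k t^2} dt / int e^{k t^2} dt on [0, 1]
  oracle <- function(k) {
    num <- integrate(function(t) t^2 * exp(k * (t^2 - 1)), 0, 1,
                     rel.tol = 1e-12)$value
    den <- integrate(function(t) exp(k * (t^2 - 1)), 0, 1,
                     rel.tol = 1e-12)$value
    num / den
  }
  for (k in c(1e-6, 0.01, 0.5, 1, 5, 20, 64, 150, 1000))
    expect_equal(watson_tau1(k), oracle(k), tolerance = 1e-8)
  # monotone increasing in kappa
  ks <- seq(0, 50, by = 0.5)
  expect_true(all(diff(watson_tau1(ks)) > 0))
})

test_that("ODI is a strictly decreasing bijection of kappa", {
  ks <- c(0.01, 0.1, 1, 10, 100)
  od <- odi_from_kappa(ks)
  expect_true(all(diff(od) < 0))
  expect_equal(kappa_from_odi(od), ks, tolerance = 1e-10)
  expect_equal(odi_from_kappa(0), 1)
})

test_that("forward model honors its limiting cases", {
  sch <- baseline_dwi_scheme()
  quad <- watson_quadrature()
  b0 <- sch$bvals < 50

  A <- noddi_forward(0.6, 0.1, 3, c(0, 0, 1), sch, quad)
  expect_equal(A[b0], rep(1, sum(b0)))  # normalization at b = 0
  expect_true(all(A > 0 & A <= 1 + 1e-12))

  # pure free water: isotropic mono-exponential decay
  A_fw <- noddi_forward(0.5, 1, 2, c(0, 0, 1), sch, quad)
  expect_equal(A_fw, exp(-sch$bvals * 3.0e-3), tolerance = 1e-12)

  # parallel sticks: no decay across, full decay along the axis (a sharp
  # Watson peak needs a denser quadrature rule)
  mu <- c(0, 0, 1)
  A_st <- noddi_forward(1, 0, kappa_from_odi(0.001), mu, sch,
                        watson_quadrature(128, 64))
  along <- which(abs(sch$bvecs %*% mu) > 0.999 & sch$bvals == 1000)
  perp <- which(abs(sch$bvecs %*% mu) < 0.02 & sch$bvals == 1000)
  if (length(along))
    expect_equal(A_st[along],
                 rep(exp(-1000 * 1.7e-3), length(along)), tolerance = 5e-3)
  expect_true(all(abs(A_st[perp] - 1) < 5e-3))
})

test_that("noise-free fit recovers the generating parameters", {
  sch <- baseline_dwi_scheme()
  quad <- watson_quadrature()
  mu <- c(sin(1.1) * cos(0.4), sin(1.1) * sin(0.4), cos(1.1))
  sig <- 850 * noddi_forward(0.55, 0.12, kappa_from_odi(0.25), mu, sch, quad)
  f <- fit_noddi(sig, sch, quad)
  expect_true(f$converged)
  expect_equal(f$v_ic, 0.55, tolerance = 5e-3)
  expect_equal(f$odi, 0.25, tolerance = 5e-3)
  expect_equal(f$v_iso, 0.12, tolerance = 5e-3)
  expect_gt(abs(sum(f$mu * mu)), 0.999)
})

test_that("free-water-only voxels bound the unidentifiable parameters", {
  sch <- baseline_dwi_scheme()
  quad <- watson_quadrature()
  sig <- 1000 * noddi_forward(0.4, 1, 5, c(0, 0, 1), sch, quad)
  f <- fit_noddi(sig, sch, quad)
  expect_gte(f$v_iso, 0.95)
  expect_true(f$v_ic >= 0 && f$v_ic <= 1)
  expect_true(f$odi > 0 && f$odi <= 1)
})

test_that("fit is invariant under consistent volume permutation", {
  sch <- baseline_dwi_scheme()
  quad <- watson_quadrature()
  sig <- 1000 * noddi_forward(0.6, 0.08, kappa_from_odi(0.3), c(0, 1, 0),
                              sch, quad)
  set.seed(4)
  perm <- sample(length(sig))
  sch_p <- dwi_scheme(sch$bvals[perm], sch$bvecs[perm, ])
  f1 <- fit_noddi(sig, sch, quad)
  f2 <- fit_noddi(sig[perm], sch_p, quad)
  expect_equal(f1$v_ic, f2$v_ic, tolerance = 1e-6)
  expect_equal(f1$odi, f2$odi, tolerance = 1e-6)
  expect_equal(f1$v_iso, f2$v_iso, tolerance = 1e-6)
})

test_that("the fit rejects schemes without multishell coverage", {
  expect_error(fit_noddi(rep(1, 72), followup_dwi_scheme()),
               "two nonzero shells")
})
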
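# Iterated-WLS tensor fit

test_that("isotropic and anisotropic reference tensors are recovered", {
  sch <- baseline_dwi_scheme()

  f_iso <- fit_dti_wls(tensor_signals(sch, rep(1e-3, 3)), sch)
  expect_equal(f_iso$fa, 0, tolerance = 1e-9)
  expect_equal(f_iso$md, 1e-3, tolerance = 1e-12)

  f_ani <- fit_dti_wls(tensor_signals(sch, c(1.5, 0.3, 0.3) * 1e-3), sch)
  expect_equal(f_ani$md, 0.7e-3, tolerance = 0.7e-3 * 1e-9)
  fa_closed <- sqrt(0.5 * ((1.5 - 0.3)^2 + 0 + (0.3 - 1.5)^2) /
                      (1.5^2 + 0.3^2 + 0.3^2))
  expect_equal(f_ani$fa, fa_closed, tolerance = 1e-9)

  # near-stick limit drives FA toward 1
  f_st <- fit_dti_wls(tensor_signals(sch, c(1.7e-3, 1e-9, 1e-9)), sch)
  expect_gt(f_st$fa, 0.999)
})

test_that("noise-free fits reproduce random rotated tensors to 1e-9", {
  sch <- baseline_dwi_scheme()
  set.seed(12)
  for (i in 1:20) {
    ev <- sort(runif(3, 0.2e-3, 2e-3), decreasing = TRUE)
    R <- random_rotation()
    f <- fit_dti_wls(tensor_signals(sch, ev, R, s0 = 500), sch)
    expect_equal(f$evals, ev, tolerance = 1e-9)
    expect_equal(exp(f$log_s0), 500, tolerance = 1e-6)
    D <- R %*% diag(ev) %*% t(R)
    expect_lt(max(abs(f$tensor - D)) / max(ev), 1e-9)
  }
})

test_that("only the single-shell subset informs the tensor", {
  sch <- baseline_dwi_scheme()
  s <- tensor_signals(sch, c(1.2, 0.5, 0.4) * 1e-3)
  s2 <- s
  high <- sch$bvals %in% c(200, 600, 2000)
  s2[high] <- 99  # corrupt every excluded shell
  f1 <- fit_dti_wls(s, sch)
  f2 <- fit_dti_wls(s2, sch)
  expect_identical(f1$fa, f2$fa)
  expect_identical(f1$md, f2$md)
})

test_that("WLS agrees with an independent weighted regression solver", {
  sch <- single_shell_scheme(baseline_dwi_scheme())
  set.seed(3)
  s <- tensor_signals(sch, c(1.4, 0.6, 0.5) * 1e-3, random_rotation(),
                      s0 = 300)
  s_noisy <- abs(s + rnorm(length(s), sd = 300 / 30))
  f <- fit_dti_wls(s_noisy, sch, n_iter = 2)
  # replicate the two reweighting rounds with stats::lm.wfit
  X <- wmhtraj:::dti_design(sch)
  y <- log(pmax(s_noisy, min(s_noisy[s_noisy > 0])))
  beta <- coef(lm(y ~ X - 1))
  for (it in 1:2) {
    w <- as.vector(exp(X %*% beta))^2
    beta <- coef(stats::lm.wfit(X, y, w))
  }
  D <- wmhtraj:::tensor_from_beta(beta)
  ev <- pmax(eigen(D, symmetric = TRUE)$values, 1e-12)
  expect_equal(f$md, mean(ev), tolerance = 1e-10)
  expect_equal(f$fa, fa_from_eigenvalues(ev), tolerance = 1e-10)
})

test_that("degenerate inputs are flagged, bounded and replaced", {
  sch <- baseline_dwi_scheme()
  # all-zero voxel: non-converged
  f0 <- fit_dti_wls(rep(0, length(sch$bvals)), sch)
  expect_false(f0$converged)
  expect_true(is.na(f0$fa))

  # nonpositive signals replaced by the smallest positive one
  s <- tensor_signals(sch, c(1.0, 0.8, 0.6) * 1e-3)
  s[sch$single_shell_subset[2]] <- 0
  expect_silent(f <- fit_dti_wls(s, sch))
  expect_true(f$fa >= 0 && f$fa <= 1)

  # rank-deficient direction set: flagged
  bad <- dwi_scheme(c(rep(0, 4), rep(1000, 8)),
                    rbind(matrix(0, 4, 3),
                          matrix(rep(c(1, 0, 0), 8), ncol = 3,
                                 byrow = TRUE)))
  fb <- fit_dti_wls(rep(1, 12), bad)
  expect_false(fb$converged)
})

test_that("FA stays in [0, 1] for noisy fits after eigenvalue clamping", {
  sch <- followup_dwi_scheme()
  set.seed(99)
  n <- 10000
  base <- tensor_signals(sch, c(1.5, 0.4, 0.3) * 1e-3, s0 = 1)
  S <- matrix(rep(base, each = n), n) * 30
  S <- sqrt((S + matrix(rnorm(n * length(base)), n))^2 +
              matrix(rnorm(n * length(base)), n)^2)  # SNR 30 Rician
  fas <- apply(S, 1, function(s) fit_dti_wls(s, sch)$fa)
  expect_true(all(fas >= 0 & fas <= 1))
})
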
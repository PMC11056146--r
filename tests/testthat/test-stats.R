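# Repeated-measures battery: GG epsilon, RM-ANOVA, Tukey HSD, paired t,
# Holm adjustment

test_that("gg_epsilon attains its closed-form limits", {
  set.seed(2)
  expect_equal(gg_epsilon(matrix(rnorm(40), 20, 2)), 1)  # k = 2 always

  Xcs <- make_cs_data(15, 4)
  expect_equal(gg_epsilon(Xcs), 1, tolerance = 1e-8)

  # rank-1 centered covariance: epsilon at the 1/(k-1) lower bound
  v <- c(3, -1, -1, -1)
  X1 <- outer(rnorm(30), v) + rnorm(30)  # subject offsets are centered out
  expect_equal(gg_epsilon(X1), 1 / 3, tolerance = 1e-10)

  expect_warning(e0 <- gg_epsilon(outer(rnorm(10), rep(1, 4))), "zero")
  expect_equal(e0, 1)
  # bounds on random data
  for (i in 1:50) {
    e <- gg_epsilon(matrix(rnorm(60), 15, 4))
    expect_true(e >= 1 / 3 && e <= 1)
  }
})

test_that("RM-ANOVA reproduces a hand-computed table and base aov", {
  X <- matrix(c(4, 6, 5,
                7, 9, 9,
                3, 5, 4,
                5, 8, 6,
                6, 7, 8), 5, 3, byrow = TRUE)
  # sums of squares by hand: SS_cond = n * sum((colmean - grand)^2), etc.
  grand <- mean(X)
  ss_cond <- 5 * sum((colMeans(X) - grand)^2)
  resid <- sweep(sweep(X, 1, rowMeans(X)), 2, colMeans(X)) + grand
  ss_err <- sum(resid^2)
  F_hand <- (ss_cond / 2) / (ss_err / 8)
  a <- rm_anova_gg(X)
  expect_equal(a$F, F_hand, tolerance = 1e-10)
  expect_equal(a$df_error, 8)
  # cross-check against aov with an Error stratum
  df <- data.frame(y = as.vector(X),
                   subj = factor(rep(1:5, 3)),
                   cond = factor(rep(1:3, each = 5)))
  fit <- summary(aov(y ~ cond + Error(subj / cond), data = df))
  tab <- fit[["Error: subj:cond"]][[1]]
  expect_equal(a$F, tab[grep("cond", rownames(tab)), "F value"],
               tolerance = 1e-10)
  expect_equal(a$p,
               pf(a$F, a$epsilon * 2, a$epsilon * 8, lower.tail = FALSE))

  # degenerate: identical conditions
  Z <- matrix(rep(rnorm(6), 3), 6, 3)
  az <- suppressWarnings(rm_anova_gg(Z))
  expect_equal(az$F, 0)
  expect_equal(az$p, 1)
  expect_error(rm_anova_gg(Z[1, , drop = FALSE]), ">= 2")
})

test_that("null rejection rate is calibrated at the nominal level", {
  # exchangeable null (equal means) with spherical covariance; the GG
  # correction should keep the type-I error near alpha
  set.seed(101)
  reps <- 4000
  rej <- 0
  for (r in seq_len(reps)) {
    X <- matrix(rnorm(20 * 4), 20)
    rej <- rej + (rm_anova_gg(X)$p < 0.05)
  }
  expect_lt(abs(rej / reps - 0.05), 0.015)
})

test_that("Tukey contrasts are additive, calibrated and conservative", {
  set.seed(7)
  X <- matrix(rnorm(48, mean = rep(c(0, 0.4, 0.9, 1.1), each = 12)), 12)
  colnames(X) <- letters[1:4]
  tk <- tukey_pairwise(X)
  expect_equal(nrow(tk), 6)
  expect_true(all(tk$ci_low <= tk$estimate & tk$estimate <= tk$ci_high))
  # chained additivity (a-b) + (b-c) = (a-c)
  est <- function(p) tk$estimate[tk$comparison == p]
  expect_equal(est("a - b") + est("b - c"), est("a - c"), tolerance = 1e-12)
  expect_equal(est("a - c") + est("c - d"), est("a - d"), tolerance = 1e-12)

  # identical condition means: all p_adj = 1, estimates 0
  Y <- matrix(rnorm(40), 10, 4)
  Y <- sweep(Y, 2, colMeans(Y))
  tk0 <- tukey_pairwise(Y)
  expect_equal(tk0$estimate, rep(0, 6), tolerance = 1e-12)
  expect_true(all(tk0$p_adj > 0.999))

  # k = 2: the studentized range collapses to the paired t test
  Z <- matrix(rnorm(30), 15, 2)
  tk2 <- tukey_pairwise(Z)
  tt <- t.test(Z[, 1], Z[, 2], paired = TRUE)
  expect_equal(tk2$p_adj, tt$p.value, tolerance = 1e-10)

  # adjustment only increases p relative to the pairwise paired t (k > 2)
  for (i in 1:30) {
    W <- matrix(rnorm(48), 12, 4)
    tkw <- tukey_pairwise(W, error = "pairwise")
    raw <- utils::combn(4, 2, function(ij)
      t.test(W[, ij[1]], W[, ij[2]], paired = TRUE)$p.value)
    expect_true(all(tkw$p_adj >= raw - 1e-12))
  }
})

test_that("paired tests match t.test and the noncentral-t power formula", {
  set.seed(13)
  bl <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, letters[1:4]))

  same <- paired_tests(bl, bl)
  expect_equal(same$estimate, rep(0, 4))
  expect_equal(same$p_raw, rep(1, 4))

  shift <- paired_tests(bl, bl + 1)
  expect_equal(shift$estimate, rep(1, 4))
  expect_equal(shift$p_raw, rep(0, 4))
  expect_equal(shift$ci_low, shift$ci_high)

  fu <- bl + matrix(rnorm(40, 0.3), 10, 4)
  pt <- paired_tests(bl, fu)
  for (j in 1:4) {
    tt <- t.test(fu[, j], bl[, j], paired = TRUE)
    expect_equal(pt$p_raw[j], tt$p.value)
    expect_equal(pt$estimate[j], unname(tt$estimate))
    expect_equal(c(pt$ci_low[j], pt$ci_high[j]), as.numeric(tt$conf.int))
  }

  # empirical power at delta = 0.5 SD, n = 100 vs the noncentral-t value
  n <- 100; delta <- 0.5
  ncp <- delta * sqrt(n)
  tcrit <- qt(0.975, n - 1)
  power_theory <- 1 - pt(tcrit, n - 1, ncp) + pt(-tcrit, n - 1, ncp)
  set.seed(17)
  hits <- 0; reps <- 1000
  zero <- matrix(0, n, 1)
  for (r in seq_len(reps)) {
    pr <- paired_tests(zero, matrix(rnorm(n, delta), n, 1))
    hits <- hits + (pr$p_raw < 0.05)
  }
  expect_equal(hits / reps, power_theory,
               tolerance = 3 * sqrt(power_theory * (1 - power_theory) / reps))
})

test_that("Holm adjustment is exact, monotone and matches p.adjust", {
  expect_equal(holm_adjust(0.03), 0.03)
  expect_error(holm_adjust(c(0.1, 1.2)), "0, 1")

  set.seed(19)
  for (i in 1:200) {
    p <- runif(sample(2:15, 1))
    h <- holm_adjust(p)
    expect_equal(h, p.adjust(p, "holm"))
    expect_true(all(h >= p & h <= 1))
    o <- order(p)
    expect_true(all(diff(h[o]) >= -1e-15))
  }
})

test_that("cohort matrices apply the complete-case rule", {
  cohort <- expand.grid(subject = 1:4, parameter = "FA",
                        class = TISSUE_CLASSES, timepoint = "bl",
                        stringsAsFactors = FALSE)
  cohort$value <- seq_len(nrow(cohort)) / 10
  cohort <- cohort[!(cohort$subject == 3 &
                       cohort$class == "regressing_wmh"), ]
  m <- cohort_matrix(cohort, "FA", "bl")
  expect_equal(rownames(m), c("1", "2", "4"))
  expect_equal(ncol(m), 4)
})
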
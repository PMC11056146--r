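# Synthetic two-timepoint subject generator

test_that("generation is deterministic and the change geometry is exact", {
  spec <- small_phantom_spec()
  a <- make_subject_phantom(spec, 5L)
  b <- make_subject_phantom(spec, 5L)
  expect_identical(a$labels_bl, b$labels_bl)
  expect_identical(a$dwi_bl$signals, b$dwi_bl$signals)
  expect_identical(a$flair_fu, b$flair_fu)
  expect_identical(a$spgr_ir_fu$signals, b$spgr_ir_fu$signals)

  # voxelwise class geometry from the truth labels
  prog <- a$trajectory == wmhtraj:::TRAJ_PROGRESSING
  reg <- a$trajectory == wmhtraj:::TRAJ_REGRESSING
  expect_true(all(a$labels_bl[prog] == wmhtraj:::LABEL_NAWM))
  expect_true(all(a$labels_fu[prog] == wmhtraj:::LABEL_WMH))
  expect_true(all(a$labels_bl[reg] == wmhtraj:::LABEL_WMH))
  expect_true(all(a$labels_fu[reg] == wmhtraj:::LABEL_NAWM))
  # all four classes populated
  expect_true(all(table(a$trajectory[a$trajectory > 0]) > 0))
  expect_length(unique(a$trajectory[a$trajectory > 0]), 4L)
  # labels differ only at change voxels
  diff_vox <- which(a$labels_bl != a$labels_fu)
  expect_setequal(diff_vox, which(prog | reg))
  # masks nest correctly; WMH and stroke never overlap
  expect_true(all(a$stroke_mask <= a$brain_mask))
  expect_false(any(a$labels_bl == wmhtraj:::LABEL_WMH & a$stroke_mask))
  # both grids span one physical extent
  expect_equal(spec$grid_shape_structural * spec$voxel_mm_structural,
               spec$grid_shape_diffusion * spec$voxel_mm_diffusion)
})

test_that("edge-case specs produce the stated geometries", {
  empty <- make_subject_phantom(small_phantom_spec(
    n_lesions = 0L, n_de_novo = 0L, fraction_progressing = 0,
    fraction_regressing = 0), 3L)
  expect_equal(sum(empty$labels_bl == wmhtraj:::LABEL_WMH), 0)
  expect_equal(sum(empty$labels_fu == wmhtraj:::LABEL_WMH), 0)

  frozen <- make_subject_phantom(small_phantom_spec(
    fraction_progressing = 0, fraction_regressing = 0, n_de_novo = 0L), 3L)
  expect_identical(frozen$labels_bl == wmhtraj:::LABEL_WMH,
                   frozen$labels_fu == wmhtraj:::LABEL_WMH)

  expect_error(phantom_spec(fraction_progressing = 0.7,
                            fraction_regressing = 0.5), "fractions")
  expect_error(phantom_spec(snr = 0), "snr")
  expect_error(phantom_spec(grid_shape_diffusion = c(20L, 24L, 24L)),
               "extent")
})

test_that("diffusion signals are nonnegative with the Rician floor", {
  sch <- followup_dwi_scheme()
  n <- 10000
  params <- list(v_ic = rep(0.5, n), v_iso = rep(0.1, n),
                 kappa = rep(3, n),
                 mu = matrix(rep(c(0, 0, 1), n), 3), s0 = 100)
  S <- simulate_dwi(params, sch, snr = 30, seed = 8)
  expect_true(all(S >= 0))
  # at high b the magnitude mean exceeds the noise-free signal
  noise_free <- simulate_dwi(params, sch, snr = Inf)
  high_b <- which(sch$bvals == 1000)[1]
  expect_gt(mean(S[, high_b]), noise_free[1, high_b])
  # Monte-Carlo agreement with the analytic Rician mean
  nu <- noise_free[1, high_b]
  sg <- 100 / 30
  x <- -nu^2 / (2 * sg^2)
  # exp(x/2) cancels against the exponentially-scaled Bessel functions
  rice_mean <- sg * sqrt(pi / 2) *
    ((1 - x) * besselI(-x / 2, 0, TRUE) - x * besselI(-x / 2, 1, TRUE))
  expect_equal(mean(S[, high_b]), rice_mean, tolerance = 0.01)

  # b = 0 returns S0 exactly without noise; pure free water decays
  # isotropically
  expect_equal(noise_free[1, 1], 100, tolerance = 1e-12)
  fw <- simulate_dwi(list(v_ic = 0.3, v_iso = 1, kappa = 1,
                          mu = matrix(c(0, 0, 1), 3), s0 = 50),
                     sch, snr = Inf)
  expect_equal(as.vector(fw), 50 * exp(-sch$bvals * 3e-3),
               tolerance = 1e-12)
  expect_error(simulate_dwi(params, sch, snr = -1), "snr")
})

test_that("FLAIR contrast separates WMH from brain as configured", {
  spec <- small_phantom_spec()
  ph <- make_subject_phantom(spec, 9L)
  wmh <- ph$labels_bl == wmhtraj:::LABEL_WMH
  brain_only <- ph$brain_mask & !wmh & !ph$stroke_mask
  expect_equal(mean(ph$flair_bl[wmh]) - mean(ph$flair_bl[brain_only]),
               spec$flair_contrast * spec$flair_sd, tolerance = 1)
  expect_true(all(ph$flair_bl[!ph$brain_mask] == 0))
  expect_error(simulate_flair(ph$labels_bl, ph$labels_bl * 0, sd = 0),
               "positive")
})

test_that("cohorts are reproducible with subject-level heterogeneity", {
  spec <- small_phantom_spec()
  c1 <- make_cohort(2, spec, seed = 21)
  c2 <- make_cohort(2, spec, seed = 21)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$subjects[[2]]$dwi_fu$signals,
                   c2$subjects[[2]]$dwi_fu$signals)
  # distinct subjects differ
  expect_false(identical(c1$subjects[[1]]$labels_bl,
                         c1$subjects[[2]]$labels_bl))
  expect_error(make_cohort(1, spec), "n_subjects")

  # zero programmed effects give equal true class means at both visits
  spec0 <- small_phantom_spec()
  spec0$longitudinal_effects[, c("d_ndi", "d_odi", "d_fwf", "d_t1")] <- 0
  ph <- make_subject_phantom(spec0, 4L)
  tr <- ph$truth
  w <- merge(tr[tr$timepoint == "bl", ], tr[tr$timepoint == "fu", ],
             by = c("class", "parameter"))
  expect_equal(w$true_mean.x, w$true_mean.y, tolerance = 1e-12)
})

test_that("subject phantoms persist to standard on-disk formats", {
  skip_if_not_installed("jsonlite")
  spec <- small_phantom_spec()
  ph <- make_subject_phantom(spec, 2L)
  dir <- file.path(tempdir(), "phantom_io")
  write_subject_phantom(ph, dir)
  lb <- read_volume_nifti(file.path(dir, "labels_bl.nii.gz"))
  expect_equal(array(as.integer(lb$data), dim(ph$labels_bl)), ph$labels_bl)
  expect_equal(lb$voxel_mm, ph$voxel_mm_structural, ignore_attr = TRUE)
  sch <- read_fsl_scheme(file.path(dir, "dwi_bl"))
  expect_equal(sch$bvals, ph$dwi_bl$scheme$bvals)
  prot <- read_qt1_protocol(file.path(dir, "qt1_protocol_fu.json"))
  expect_equal(prot$ir_ti_ms, 600)
  truth <- read.csv(file.path(dir, "truth.csv"))
  expect_equal(nrow(truth), nrow(ph$truth))
})
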
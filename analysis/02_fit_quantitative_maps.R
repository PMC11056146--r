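#!/usr/bin/env Rscript
# Fit the quantitative maps for the subject simulated by 01_simulate_phantom
# and check each fitter against the subject's ground truth: the tensor fit
# (FA/MD) on the single-shell subset, DESPOT1-HIFI T1 (with the baseline B1
# re-used at follow-up), and Watson-NODDI on a subsample of white-matter
# voxels at baseline.

library(wmhtraj)

spec <- phantom_spec()
subject <- make_subject_phantom(spec, subject_seed = 1L)
out <- file.path("results", "maps_subject01")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

# masks in diffusion space from the ground-truth trajectory labels
traj_d <- resample_nn(subject$trajectory, subject$voxel_mm_structural,
                      subject$dwi_bl$grid_shape,
                      subject$voxel_mm_diffusion)
masks_d <- list(stable_nawm = traj_d == 1L, stable_wmh = traj_d == 2L,
                progressing_wmh = traj_d == 3L, regressing_wmh = traj_d == 4L)
union_d <- Reduce(`|`, masks_d)

rows <- list()
for (tp in c("bl", "fu")) {
  dw <- subject[[paste0("dwi_", tp)]]
  fit <- fit_dti_map(dw$signals, dw$voxels, dw$grid_shape, union_d,
                     dw$scheme)
  write_volume_nifti(fit$fa, file.path(out, sprintf("fa_%s.nii.gz", tp)),
                     subject$voxel_mm_diffusion)
  write_volume_nifti(fit$md, file.path(out, sprintf("md_%s.nii.gz", tp)),
                     subject$voxel_mm_diffusion)
  rows[[tp]] <- data.frame(timepoint = tp,
                           class = names(masks_d),
                           fa = class_means(fit$fa, masks_d, fit$converged),
                           md = class_means(fit$md * 1e3, masks_d,
                                            fit$converged))
}

# T1: full HIFI at baseline, B1 carried to the sparse follow-up protocol
union_s <- subject$trajectory > 0L
t1_bl <- fit_t1_map(subject$spgr_ir_bl$signals, union_s,
                    subject$spgr_ir_bl$protocol)
t1_fu <- fit_t1_map(subject$spgr_ir_fu$signals, union_s,
                    subject$spgr_ir_fu$protocol, b1_fixed = t1_bl$b1)
write_volume_nifti(t1_bl$t1, file.path(out, "t1_bl.nii.gz"),
                   subject$voxel_mm_structural)
write_volume_nifti(t1_fu$t1, file.path(out, "t1_fu.nii.gz"),
                   subject$voxel_mm_structural)
masks_s <- list(stable_nawm = subject$trajectory == 1L,
                stable_wmh = subject$trajectory == 2L,
                progressing_wmh = subject$trajectory == 3L,
                regressing_wmh = subject$trajectory == 4L)
for (tp in c("bl", "fu")) {
  f <- if (tp == "bl") t1_bl else t1_fu
  rows[[tp]]$t1 <- class_means(f$t1, masks_s, f$converged)
}

measured <- do.call(rbind, rows)
truth <- subject$truth
long <- reshape(measured, direction = "long",
                varying = c("fa", "md", "t1"),
                v.names = "value", timevar = "parameter",
                times = c("FA", "MD", "T1"))
cmp <- merge(long, truth, by.x = c("class", "timepoint", "parameter"),
             by.y = c("class", "timepoint", "parameter"))
cmp$abs_err <- abs(cmp$value - cmp$true_mean)
write.csv(cmp[order(cmp$parameter, cmp$class, cmp$timepoint),
              c("parameter", "class", "timepoint", "value", "true_mean",
                "abs_err")],
          file.path(out, "class_means_vs_truth.csv"), row.names = FALSE)
message("class-mean recovery (max |error| per parameter):")
print(tapply(cmp$abs_err, cmp$parameter, max), digits = 3)

# NODDI on a class-stratified white-matter subsample at baseline
set.seed(2)
sub_mask <- array(FALSE, subject$dwi_bl$grid_shape)
for (m in masks_d) {
  vox <- which(m)
  if (length(vox))
    sub_mask[sample(vox, min(15, length(vox)))] <- TRUE
}
sub_mask <- sub_mask & union_d
nod <- fit_noddi_map(subject$dwi_bl$signals, subject$dwi_bl$voxels,
                     subject$dwi_bl$grid_shape, sub_mask,
                     subject$dwi_bl$scheme)
nod_means <- data.frame(
  class = names(masks_d),
  ndi = class_means(nod$ndi, masks_d, nod$converged),
  odi = class_means(nod$odi, masks_d, nod$converged),
  fwf = class_means(nod$fwf, masks_d, nod$converged))
write.csv(nod_means, file.path(out, "noddi_subsample_means.csv"),
          row.names = FALSE)
message("NODDI subsample class means:")
print(nod_means, digits = 3)
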
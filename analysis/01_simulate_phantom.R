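#!/usr/bin/env Rscript
# Simulate one two-timepoint synthetic subject and persist every modality.
#
# Writes results/subject01/: label and FLAIR NIfTIs for both visits,
# multishell + single-shell diffusion series with FSL gradient tables,
# SPGR/IR-SPGR stacks with JSON protocol descriptors, masks, the lesion
# template prior, and the ground-truth class/parameter table.

library(wmhtraj)

spec <- phantom_spec()
subject <- make_subject_phantom(spec, subject_seed = 1L)
out <- file.path("results", "subject01")
write_subject_phantom(subject, out)

vol <- class_volumes(list(
  stable_nawm = subject$trajectory == 1L,
  stable_wmh = subject$trajectory == 2L,
  progressing_wmh = subject$trajectory == 3L,
  regressing_wmh = subject$trajectory == 4L
), subject$voxel_mm_structural)
write.csv(vol, file.path(out, "true_class_volumes.csv"), row.names = FALSE)

message("subject written to ", out)
message("true class volumes (mL):")
print(vol)
message("ground-truth longitudinal effects (per class, truth table):")
tr <- subject$truth
w <- merge(tr[tr$timepoint == "bl", ], tr[tr$timepoint == "fu", ],
           by = c("class", "parameter"), suffixes = c("_bl", "_fu"))
w$change <- w$true_mean_fu - w$true_mean_bl
print(w[w$parameter %in% c("FA", "MD", "T1"),
        c("class", "parameter", "true_mean_bl", "change")], digits = 3)
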
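#!/usr/bin/env Rscript
# The flagship analysis: a 20-subject synthetic cohort through the full
# pipeline, then the statistical battery — per-parameter repeated-measures
# ANOVAs with Greenhouse-Geisser correction and Tukey HSD contrasts at both
# visits, and paired baseline-vs-1-year t tests with one Holm family across
# all 12 (parameter, class) rows. Tables land in results/cohort/.

library(wmhtraj)

cfg <- run_config(spec = phantom_spec(), n_subjects = 20L, seed = 20240131L)
res <- suppressWarnings(run_cohort(cfg))
out <- file.path("results", "cohort")
report_tables(res, out)

message("repeated-measures ANOVA (GG-corrected):")
print(res$anova, digits = 4)
message("paired baseline-vs-1-year tests with Holm adjustment:")
print(res$paired, digits = 3)
message("direction pattern against the cohort's own ground truth:")
sp <- res$sign_summary
print(sp[, c("parameter", "class", "estimate", "p_holm",
             "expected_effect", "ok")], digits = 3)
message("all programmed directions recovered: ", attr(sp, "all_match"))
message("tables written to ", out)
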
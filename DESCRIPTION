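Package: wmhtraj
Title: Tissue Signatures of Longitudinal White Matter Hyperintensity Change
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for quantitative-MRI tissue
    signatures of white matter hyperintensity (WMH) change in cerebral small
    vessel disease. Generates two-timepoint synthetic subjects (FLAIR-like
    volumes, multishell diffusion, variable-flip-angle SPGR/IR-SPGR) with
    known ground truth; fits diffusion tensors (FA, MD), Watson-NODDI
    microstructure (NDI, ODI, FWF) and DESPOT1-HIFI T1 maps from raw
    signals; segments WMHs by hierarchical intensity thresholding; derives
    the four longitudinal tissue classes (stable NAWM, stable WMH,
    progressing WMH, regressing WMH); and runs the repeated-measures
    statistical battery (Greenhouse-Geisser corrected ANOVA, Tukey HSD,
    paired t tests with Holm correction) on per-class mean signatures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    pracma,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
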
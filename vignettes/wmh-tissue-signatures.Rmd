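---
title: "Tissue signatures of white matter hyperintensity change: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue signatures of white matter hyperintensity change: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmhtraj)
```

## The scientific question

White matter hyperintensities (WMHs) are bright regions on FLAIR MRI that
mark white-matter damage in cerebral small vessel disease. WMHs mostly
grow over time, but discrete areas can also *regress* — revert to
normal-appearing white matter (NAWM) — within the same person. Whether
regression reflects genuine tissue improvement or measurement noise can
be probed with quantitative MRI: if voxels that regress carry distinct,
less-damaged tissue signatures (higher fractional anisotropy FA, lower
mean diffusivity MD, lower T1, higher neurite density NDI) than voxels
that stay WMH, regression is a real tissue state, not an artifact.

This package rebuilds that analysis as a fully simulated, ground-truthed
pipeline. Two aligned visits a year apart define four voxel classes:
stable NAWM, stable WMH, progressing WMH (NAWM at baseline, WMH at one
year) and regressing WMH (the reverse). Per-class mean quantitative
parameters feed a repeated-measures statistical battery. Because the real
cohort's raw MRI is not publicly deposited, a synthetic-subject generator
stands in for the scanner, with every downstream quantity checkable
against known truth.

## The generative model

### Geometry

A subject is an ellipsoidal "brain" on a 48^3 structural grid (1 mm
isotropic) containing an ellipsoidal white-matter shell around a central
non-WM core, 20 spherical WMH lesions (radius 2–5 mm) placed inside the
WM, and one spherical stroke lesion that is excluded from all WMH
accounting. The diffusion grid is 24^3 at 2 mm over the same 48 mm field
of view, so nearest-neighbour resampling between the grids is exact and
well-posed. These desk-scale sizes keep a full cohort analysis in the
minutes range; nothing in the pipeline depends on them.

Longitudinal change is anchored to lesions rather than scattered voxels,
because incident WMH voxels overwhelmingly appear at the edge of existing
lesions: a progressing lesion grows a one-voxel rim (plus a small number
of de novo lesions), a regressing lesion loses its boundary rim. Whole
lesions are assigned to progression (default 35%) or regression (30%);
rims are therefore contiguous clusters that survive the <5-voxel filter,
while lesion cores remain stable WMH. Where regression actually occurs
spatially in vivo is not established; rim erosion is a modeling
convenience and the fractions are set so the volume ratios of the four
classes resemble a mild-stroke SVD cohort (stable WMH of order 10 mL,
change classes of order 1–3 mL).

### Signals

*Diffusion.* Every voxel's diffusion signal, at both visits, comes from
one generative model: the three-compartment Watson-NODDI model with fixed
intrinsic diffusivities d_par = 1.7e-3 and d_iso = 3.0e-3 mm^2/s, the
standard in-vivo defaults. The intracellular compartment integrates a
stick response over a Watson orientation density (spherical quadrature,
60 Gauss–Legendre nodes in cos(theta) x 48 azimuths, antipodally folded);
the extracellular tensor is tortuosity-coupled (d_perp = d_par(1 - NDI))
through the Watson moment tau1, computed from a Dawson-function closed
form that agrees with adaptive quadrature to 1e-8. The baseline
acquisition has shells b = 0 (15), 200 (3), 600 (6), 1000 (64), 2000 (64)
s/mm^2; the 1-year visit only b = 0 (8) + 1000 (64). Noise is Rician:
magnitude of signal plus complex Gaussian with SD = S0/SNR, SNR = 30 at
b = 0.

Because the diffusion generative model is NODDI, FA and MD are *derived*
quantities: the ground-truth FA/MD of a tissue class is defined as the
noise-free tensor fit of that class's NODDI signal on the single-shell
subset — the same deterministic map the analysis itself applies. This
keeps one coherent forward model rather than two competing ones, and it
means longitudinal FA/MD effects are programmed in NODDI-parameter space;
the induced FA/MD changes are recorded per subject in the truth table.

*Relaxometry.* T1 maps generate SPGR and IR-SPGR volumes: three flip
angles (2, 5, 12 degrees) plus two inversion times (600, 1500 ms) at
baseline; two angles (2, 12) plus TI = 600 ms at one year; TR = 10 ms. A
smooth B1 field (about +/-15%) scales all nominal flip angles. Noise is
Gaussian at SNR 150 relative to the mean volume signal — relaxometry
volumes are acquired at structural resolution and are far less noisy than
diffusion EPI, and the Gaussian (not Rician) choice matches
high-SNR magnitude data where the fit is effectively unbiased.

*FLAIR.* Brain-tissue intensity is Normal(100, 10); voxels that are WMH
(or stroke) at a visit sit `flair_contrast` brain-SDs higher, default 4 —
the conspicuity of an established WMH core. At contrast 3 the per-voxel
detection probability under the 1.69-SD rule drops to about 0.8 and
independently thresholded visits disagree on a large fraction of boundary
voxels; that regime is retained as a stress test of the segmentation
(the Dice acceptance check runs there) but is not a realistic default.

### Subject and voxel heterogeneity

Each subject draws class-mean parameters from Normal(population mean,
between-subject SD) and a subject-specific longitudinal effect
(SD = 20% of the effect). Voxels add a small within-class deviation
(SD 0.015 for the volume fractions; 0.03 s for T1) that is drawn *once*
and shared by both visits, so the within-voxel true change equals the
programmed effect exactly. This gives the repeated-measures model a true
subject effect and keeps paired differences clean.

### Default class parameters

The baseline class means encode the cross-sectional ordering reported
for SVD cohorts: NDI and FA highest in stable NAWM, lowest in stable
WMH, progressing slightly above regressing at baseline; ODI highest in
NAWM; FWF, MD and T1 lowest in NAWM, highest in stable WMH; baseline T1
in regressing above progressing. Longitudinal effects encode the
published direction pattern: FA falls while MD and T1 rise in progressing
and stable WMH; MD (and marginally T1) rise slightly in stable NAWM; and
in regressing WMH, FA rises while MD and T1 barely move. The regressing
entries trade a small NDI increase and ODI decrease against a slight FWF
increase precisely so the induced MD change is near zero.

## The fitted models

*Tensor (FA/MD).* Log-linear least squares on ln S = ln S0 - b g'Dg over
the b in {0, 1000} subset only (so both visits are fitted identically),
reweighted twice with weights equal to squared predicted signals;
eigenvalues clamped at 1e-12 so FA stays in [0, 1] under noise;
nonpositive signals replaced by the voxel's smallest positive signal
before the log. Noise-free recovery is exact to 1e-9.

*NODDI.* Fitted only at baseline (no follow-up multishell data exist, so
NDI/ODI/FWF enter cross-sectional analyses only). Orientation is seeded
from the tensor's principal eigenvector, a 64-point coarse grid over
(NDI, FWF, ODI) picks the basin, and bounded L-BFGS-B refines all five
parameters. ODI's lower optimizer bound is 0.02 (kappa ~ 64), within the
quadrature rule's accurate range. Over a 5x5x5 truth grid the noise-free
maximum error is below 0.02 per parameter and the SNR-30 median error
below 0.05.

*DESPOT1-HIFI.* The joint (T1, M0, B1) fit minimizes the summed squared
residual of the SPGR and ideal-inversion IR-SPGR equations: B1 is
profiled on a coarse grid plus golden-section refinement with the inner
(T1, M0) solved by the linear DESPOT1 form, then a damped Gauss–Newton
polish runs on the full objective. The ideal-inversion magnitude
equation |M0 sin(B1 a)(1 - 2 exp(-TI/T1))| is a documented simplification
of the segmented-readout HIFI recursion; phantom and fitter share it, so
the analysis is self-consistent. One genuine identifiability fact drives
a pipeline choice: with only two angles and one TI the three-parameter
problem admits a second exact solution on the other branch of the IR
null (near T1 = TI/ln 2, i.e. ~0.87 s — squarely in the white-matter
range), so the 1-year fit re-uses the baseline B1 map voxelwise and
estimates only (T1, M0). B1 is set by hardware and positioning and is
the stable quantity here; with it fixed, follow-up T1 is well-posed and
noise-free recovery is exact to <0.1% on both protocols.

## Segmentation and change masks

WMH segmentation follows a hierarchical thresholding rule: candidates
are voxels above mean + 1.69 SD of brain-tissue intensity; a lesion
probability template (here: the dilated, smoothed WM mask) vetoes
candidates with prior below 0.1; the candidate indicator is smoothed
with a sigma = 0.5 voxel Gaussian and re-binarized; finally voxels with
intensity Z below 0.95 are dropped. Two choices were genuinely open:

- *What the smoothing step does.* Re-binarizing at 0.5 would make the
  smoothed value of an isolated candidate (kernel center weight ~0.49)
  decisive, so the step would only erode; interior voxels that narrowly
  miss the intensity threshold would stay holes, and independently
  segmented visits would flicker voxelwise, manufacturing spurious
  "change". The step is instead treated as refinement: re-binarization at
  support 0.25 (below the center weight) fills interior holes and drops
  unsupported voxels, after which the Z-floor removes genuinely dim
  fill-ins. This keeps the documented monotonicity property (raising the
  threshold never adds voxels).
- *The Z-score referent.* The Z rule uses the same brain-tissue mean/SD
  as the 1.69-SD rule, computed on raw intensities; the configuration
  exposes both numbers.

NAWM is WM minus WMH minus stroke, by construction disjoint from both.
The four change classes are plain voxelwise intersections of the
two-visit masks; voxels entering or leaving the stroke mask belong to no
class. Cluster filtering removes connected components under 5 voxels
(26-neighbourhood by default; 6 available) from each class mask — *after*
structural-space volumetrics, *before* nearest-neighbour resampling onto
the diffusion grid, mirroring the partial-volume rationale: 5 structural
voxels is just over half a 2 mm diffusion voxel. Whether the original
rule used 6- or 26-connectivity is not stated anywhere; 26 is the common
3-D morphology default.

## Statistics

Per parameter and visit, the four class means per subject enter a
one-way repeated-measures ANOVA (complete cases only). Sphericity is
never assumed: the Greenhouse–Geisser epsilon — eigenvalue form on the
double-centered covariance, clipped to [1/(k-1), 1] — multiplies both
degrees of freedom. Tukey HSD contrasts use the pooled within-subject
MS_error with the studentized-range distribution on (k-1)(n-1) df; a
`pairwise` flag switches to per-pair paired-difference SEs as a
sensitivity analysis, and the CI/df choice is exposed because the
original post hoc error term is not printed anywhere. Longitudinal
change is tested by classical paired t tests per class, with a single
Holm step-down family across all 12 (parameter, class) rows — the family
size back-calculates unambiguously from the published adjusted values
(0.017 -> 0.068 requires rank 9 of 12). Two-sided tests, alpha 0.05, 95%
CIs throughout.

The type-I error of the GG-corrected ANOVA is verified by simulation
under a strongly heteroscedastic null (condition variances 16:1:1:1,
equal means; n = 20, k = 4): the empirical size at 10^4 replicates sits
within 0.05 +/- 0.006, where the uncorrected F test would be badly
anticonservative. Under exact compound symmetry the epsilon estimate
equals 1 to 1e-8 (the test constructs data whose *sample* covariance is
exactly compound-symmetric; a random draw from a CS population would
not be).

## What the phantom does and does not show

Passing this suite demonstrates that the pipeline's arithmetic is right:
the fitters invert their own forward models at known truth, the mask
logic is exact, the statistics are calibrated, and an effect pattern
programmed into tissue microstructure survives the full
segmentation-classification-measurement chain at realistic noise. It
does not validate the biology or the acquisition: the phantom has no
real anatomy, no registration error (visits are generated pre-aligned),
no scanner artifacts, no atrophy or ventricular enlargement, and its
lesion-boundary partial volume is idealized. Results on real data also
depend on segmentation quality near boundaries — the phantom shows that
boundary flicker between independently segmented visits contaminates
precisely the regressing class, which is why the change masks' cluster
filter and a conspicuous lesion contrast matter.

## Problem sizes and runtime

Defaults used by the analysis scripts and validation suite: 48^3/24^3
grids, 20 lesions, cohorts of 20 subjects, 5x5x5 recovery grids, 10^4
calibration replicates. A full cohort analysis runs in a few minutes on
one core; per-voxel NODDI is the slow step (~0.3 s/voxel) and is
restricted to baseline class masks or subsamples where it appears.
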
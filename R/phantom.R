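# Two-timepoint synthetic subjects for the WMH-change analysis.
#
# A subject is a pair of aligned label volumes (background, non-WM brain,
# NAWM, WMH, stroke) in which a known subset of lesion voxels progresses
# (NAWM -> WMH) or regresses (WMH -> NAWM) over one year, plus the raw
# signals every downstream fit consumes: a FLAIR-like structural volume,
# multishell (baseline) and single-shell (follow-up) diffusion series
# generated from the Watson-NODDI forward model, and SPGR/IR-SPGR volume
# sets generated from the T1 map. Ground-truth per-class parameter means
# are recorded at both timepoints.

LABEL_BACKGROUND <- 0L
LABEL_NONWM <- 1L
LABEL_NAWM <- 2L
LABEL_WMH <- 3L
LABEL_STROKE <- 4L

TRAJ_NONE <- 0L
TRAJ_STABLE_NAWM <- 1L
TRAJ_STABLE_WMH <- 2L
TRAJ_PROGRESSING <- 3L
TRAJ_REGRESSING <- 4L

TISSUE_CLASSES <- c("stable_nawm", "stable_wmh", "progressing_wmh",
                    "regressing_wmh")

default_class_params <- function() {
  # baseline microstructure per trajectory class (plus non-WM brain and
  # stroke tissue). Values chosen to reproduce the published cross-sectional
  # ordering: NDI and FA highest in stable NAWM and lowest in stable WMH
  # with progressing slightly above regressing; ODI highest in NAWM; FWF,
  # MD and T1 lowest in NAWM and highest in stable WMH; baseline T1 in
  # regressing above progressing. "sd" columns are between-subject SDs,
  # "flair_c" is FLAIR contrast in brain-SD units when the class appears as
  # WMH on that visit.
  data.frame(
    class = c(TISSUE_CLASSES, "nonwm_brain", "stroke"),
    ndi = c(0.62, 0.37, 0.52, 0.50, 0.45, 0.30),
    odi = c(0.300, 0.267, 0.272, 0.272, 0.50, 0.45),
    fwf = c(0.10, 0.17, 0.13, 0.13, 0.15, 0.35),
    t1 = c(0.95, 1.30, 1.05, 1.08, 1.40, 1.60),
    ndi_sd = c(0.02, 0.025, 0.025, 0.025, 0.02, 0.03),
    odi_sd = c(0.015, 0.015, 0.015, 0.015, 0.02, 0.03),
    fwf_sd = c(0.01, 0.02, 0.015, 0.015, 0.015, 0.04),
    t1_sd = c(0.03, 0.05, 0.04, 0.04, 0.05, 0.08),
    stringsAsFactors = FALSE
  )
}

default_longitudinal_effects <- function() {
  # additive 1-year changes in microstructure space (NDI/ODI/FWF unitless,
  # T1 in seconds), chosen to realize the published direction pattern of
  # longitudinal change: FA increases only in regressing WMH; FA decreases
  # while MD and T1 increase in progressing and stable WMH; MD (and
  # slightly T1) increase and FA slightly decreases in stable NAWM.
  # FA/MD are derived quantities of the diffusion generative model, so the
  # induced FA/MD effects are recorded in the subject truth table.
  # the regressing-WMH entries trade a small NDI rise and ODI fall against
  # a slight FWF rise so the induced MD change is near zero ("little
  # change") while FA clearly increases
  data.frame(
    class = TISSUE_CLASSES,
    d_ndi = c(-0.004, -0.050, -0.060, 0.012),
    d_odi = c(0.000, 0.000, 0.000, -0.045),
    d_fwf = c(0.004, 0.030, 0.030, 0.004),
    d_t1 = c(0.005, 0.049, 0.058, -0.003),
    stringsAsFactors = FALSE
  )
}

#' Phantom specification
#'
#' Defines the geometry, tissue parameters, longitudinal effects and noise
#' of a synthetic two-timepoint subject. Defaults give a desk-scale 48^3
#' structural grid (1 mm isotropic) and 24^3 diffusion grid (2 mm
#' isotropic) over the same 48 mm field of view, 20 lesions, and the
#' class-conditional parameters listed by \code{default_class_params()}.
#'
#' @param grid_shape_structural,voxel_mm_structural structural grid.
#' @param grid_shape_diffusion,voxel_mm_diffusion diffusion grid; both
#'   grids must span the same physical extent.
#' @param n_lesions number of WMH lesions.
#' @param lesion_radius_range_mm lesion radius range, mm.
#' @param fraction_progressing,fraction_regressing fraction of lesions
#'   assigned a progression rim / a regression rim erosion; must sum to
#'   <= 1.
#' @param n_de_novo number of new (de novo) lesions appearing at follow-up.
#' @param class_params data frame of per-class parameter means and
#'   between-subject SDs (see \code{default_class_params}).
#' @param longitudinal_effects data frame of per-class additive 1-year
#'   changes (see \code{default_longitudinal_effects}).
#' @param effect_sd_frac between-subject SD of each longitudinal effect,
#'   as a fraction of its mean magnitude.
#' @param voxel_sd within-class voxel-level SD for NDI/ODI/FWF (T1 uses
#'   twice this value, in seconds).
#' @param flair_contrast WMH FLAIR contrast in brain-SD units.
#' @param flair_mean,flair_sd FLAIR brain-tissue intensity mean and SD.
#' @param flair_smooth_sigma optional partial-volume smoothing of the
#'   FLAIR volume, voxels.
#' @param snr b=0 signal over noise SD for the diffusion series; may be
#'   \code{Inf} for noise-free.
#' @param snr_qt1 mean-signal over noise SD for the SPGR/IR-SPGR volumes
#'   (structural-resolution relaxometry images run at much higher SNR than
#'   diffusion EPI).
#' @param seed integer master seed.
#' @return object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(grid_shape_structural = c(48L, 48L, 48L),
                         voxel_mm_structural = c(1, 1, 1),
                         grid_shape_diffusion = c(24L, 24L, 24L),
                         voxel_mm_diffusion = c(2, 2, 2),
                         n_lesions = 20L,
                         lesion_radius_range_mm = c(2, 5),
                         fraction_progressing = 0.35,
                         fraction_regressing = 0.30,
                         n_de_novo = 2L,
                         class_params = default_class_params(),
                         longitudinal_effects = default_longitudinal_effects(),
                         effect_sd_frac = 0.2,
                         voxel_sd = 0.015,
                         flair_contrast = 4,
                         flair_mean = 100,
                         flair_sd = 10,
                         flair_smooth_sigma = 0,
                         snr = 30,
                         snr_qt1 = 150,
                         seed = 1L) {
  spec <- structure(as.list(environment()), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

#' Validate a phantom specification
#' @param spec a \code{phantom_spec}.
#' @return invisibly TRUE; stops on violation.
#' @export
validate_phantom_spec <- function(spec) {
  ext_s <- spec$grid_shape_structural * spec$voxel_mm_structural
  ext_d <- spec$grid_shape_diffusion * spec$voxel_mm_diffusion
  if (max(abs(ext_s - ext_d)) > 1e-6)
    stop("structural and diffusion grids must cover the same physical extent")
  if (spec$fraction_progressing < 0 || spec$fraction_regressing < 0 ||
      spec$fraction_progressing + spec$fraction_regressing > 1)
    stop("change fractions must be in [0,1] and sum to <= 1")
  if (spec$snr <= 0 || spec$snr_qt1 <= 0) stop("snr must be positive")
  if (spec$flair_sd <= 0) stop("flair_sd must be positive")
  sds <- unlist(spec$class_params[grep("_sd$", names(spec$class_params))])
  if (any(sds < 0)) stop("class parameter SDs must be >= 0")
  if (spec$n_lesions < 0) stop("n_lesions must be >= 0")
  if (diff(spec$lesion_radius_range_mm) < 0)
    stop("lesion_radius_range_mm must be nondecreasing")
  invisible(TRUE)
}

# voxel-center coordinates (mm) of a grid
grid_coords <- function(shape, voxel_mm) {
  lapply(1:3, function(a) (seq_len(shape[a]) - 0.5) * voxel_mm[a])
}

ellipsoid_mask <- function(shape, voxel_mm, center_mm, semi_mm) {
  co <- grid_coords(shape, voxel_mm)
  dx2 <- ((co[[1]] - center_mm[1]) / semi_mm[1])^2
  dy2 <- ((co[[2]] - center_mm[2]) / semi_mm[2])^2
  dz2 <- ((co[[3]] - center_mm[3]) / semi_mm[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
}

sphere_mask <- function(shape, voxel_mm, center_mm, radius_mm)
  ellipsoid_mask(shape, voxel_mm, center_mm, rep(radius_mm, 3))

dilate_mask <- function(mask, connectivity = 6L) {
  off <- neighbour_offsets(connectivity)
  out <- mask
  for (r in seq_len(nrow(off))) {
    s <- mask
    for (a in 1:3) if (off[r, a] != 0) s <- shift_array(s, a, off[r, a])
    out <- out | s
  }
  out
}

boundary_voxels <- function(mask, connectivity = 6L) {
  # voxels of the mask with at least one out-of-mask neighbour
  off <- neighbour_offsets(connectivity)
  inner <- mask
  for (r in seq_len(nrow(off))) {
    s <- mask
    for (a in 1:3) if (off[r, a] != 0) s <- shift_array(s, a, off[r, a])
    inner <- inner & s
  }
  mask & !inner
}

#' Simulate diffusion-weighted signals from Watson-NODDI parameters
#'
#' Noise-free signals are S0 times the Watson-NODDI forward model at each
#' voxel's true parameters; Rician noise is then applied as the magnitude
#' of (signal + complex Gaussian) with per-channel SD = S0/snr.
#'
#' @param params list of equal-length vectors \code{v_ic}, \code{v_iso},
#'   \code{kappa}, plus \code{mu} (3 x n matrix) and optionally \code{s0}
#'   (default 1000).
#' @param scheme a \code{dwi_scheme}.
#' @param snr b=0 signal over noise SD; \code{Inf} disables noise.
#' @param seed integer seed for the noise draw.
#' @param quad quadrature rule.
#' @param chunk voxels per vectorized block.
#' @return matrix of signals, voxels x volumes.
#' @export
simulate_dwi <- function(params, scheme, snr, seed = 1L,
                         quad = watson_quadrature(), chunk = 1500L) {
  if (snr <= 0) stop("snr must be positive")
  n <- length(params$v_ic)
  stopifnot(length(params$v_iso) == n, length(params$kappa) == n,
            ncol(params$mu) == n)
  s0 <- params$s0 %||% rep(1000, n)
  if (length(s0) == 1L) s0 <- rep(s0, n)
  pre <- noddi_precompute(scheme, quad)
  nvol <- length(scheme$bvals)
  S <- matrix(0, n, nvol)
  idx <- split(seq_len(n), ceiling(seq_len(n) / chunk))
  for (ii in idx) {
    A <- noddi_forward_block(params$v_ic[ii], params$v_iso[ii],
                             params$kappa[ii],
                             params$mu[, ii, drop = FALSE], scheme, pre)
    S[ii, ] <- s0[ii] * A
  }
  if (is.finite(snr)) {
    set.seed(seed)
    sig <- s0 / snr
    n1 <- matrix(rnorm(n * nvol), n, nvol) * sig
    n2 <- matrix(rnorm(n * nvol), n, nvol) * sig
    S <- sqrt((S + n1)^2 + n2^2)
  }
  S
}

#' Simulate SPGR and IR-SPGR volume sets
#'
#' Noise-free signals follow the SPGR and ideal-inversion IR-SPGR
#' equations; independent Gaussian noise is added per volume with SD equal
#' to the mean nonzero noise-free signal divided by snr.
#'
#' @param t1_map,m0_map,b1_map 3-D arrays (T1 in seconds).
#' @param protocol a \code{qt1_protocol}.
#' @param snr signal-to-noise ratio; \code{Inf} disables noise.
#' @param seed integer seed.
#' @return 4-D array, volumes stacked SPGR-angles-then-IR along dim 4.
#' @export
simulate_spgr_ir <- function(t1_map, m0_map, b1_map, protocol, snr,
                             seed = 1L) {
  if (snr <= 0) stop("snr must be positive")
  if (any(protocol$spgr_flip_deg <= 0) || any(protocol$spgr_flip_deg > 90))
    stop("flip angles must be in (0, 90] degrees")
  d <- dim(t1_map)
  t1_ms <- t1_map * 1000
  inside <- t1_map > 0
  t1_ms[!inside] <- 1000  # placeholder; zeroed below
  vols <- c(lapply(protocol$spgr_flip_deg, function(a)
    spgr_signal(m0_map, t1_ms, b1_map, a, protocol$tr_ms)),
    lapply(protocol$ir_ti_ms, function(ti)
      ir_spgr_signal(m0_map, t1_ms, b1_map, protocol$ir_flip_deg, ti)))
  out <- array(0, dim = c(d, length(vols)))
  for (j in seq_along(vols)) {
    v <- vols[[j]]
    v[!inside] <- 0
    out[, , , j] <- v
  }
  if (is.finite(snr)) {
    set.seed(seed)
    ref <- mean(abs(out[out != 0]))
    out <- out + array(rnorm(length(out), sd = ref / snr), dim = dim(out))
    for (j in seq_along(vols)) {
      v <- out[, , , j]
      v[!inside] <- 0
      out[, , , j] <- v
    }
  }
  out
}

#' Simulate a FLAIR-like structural volume
#'
#' Brain-tissue intensity is Normal(mean, sd); voxels carrying a WMH-type
#' class at the given visit are shifted upward by \code{contrast} brain-SD
#' units. Optional Gaussian smoothing emulates partial-volume edges.
#'
#' @param labels integer label volume (see label codes in this module).
#' @param contrast_map array of per-voxel contrast in brain-SD units.
#' @param mean,sd brain intensity mean and SD; sd must be > 0.
#' @param smooth_sigma smoothing sigma in voxels (0 = off).
#' @param seed integer seed.
#' @return numeric array of intensities (0 outside the head).
#' @export
simulate_flair <- function(labels, contrast_map, mean = 100, sd = 10,
                           smooth_sigma = 0, seed = 1L) {
  if (sd <= 0) stop("brain intensity sd must be positive")
  set.seed(seed)
  brain <- labels != LABEL_BACKGROUND
  vol <- array(0, dim = dim(labels))
  vol[brain] <- mean + contrast_map[brain] * sd +
    rnorm(sum(brain), sd = sd)
  if (smooth_sigma > 0) {
    sm <- gaussian_smooth3d(vol, smooth_sigma)
    vol[brain] <- sm[brain]
  }
  vol
}

# assign per-subject class means: Normal(spec mean, spec SD), clamped to
# physical ranges
draw_subject_class_params <- function(spec) {
  cp <- spec$class_params
  out <- cp
  for (p in c("ndi", "odi", "fwf", "t1")) {
    v <- rnorm(nrow(cp), cp[[p]], cp[[paste0(p, "_sd")]])
    lim <- if (p == "t1") c(0.3, 3) else c(0.02, 0.98)
    out[[p]] <- clamp(v, lim[1], lim[2])
  }
  out
}

draw_subject_effects <- function(spec) {
  ef <- spec$longitudinal_effects
  for (p in c("d_ndi", "d_odi", "d_fwf", "d_t1")) {
    ef[[p]] <- rnorm(nrow(ef), ef[[p]], abs(ef[[p]]) * spec$effect_sd_frac)
  }
  ef
}

#' Generate one two-timepoint synthetic subject
#'
#' Builds the label geometry (brain/WM/ventricle ellipsoids, spherical WMH
#' lesions, one stroke lesion), assigns progression rims and regression rim
#' erosions to whole lesions so that change clusters are contiguous,
#' samples subject-level class parameters and longitudinal effects, and
#' synthesizes all raw signals. Deterministic given (spec, subject_seed).
#'
#' @param spec a \code{phantom_spec}.
#' @param subject_seed integer seed for this subject.
#' @return object of class \code{subject_phantom}: label volumes and
#'   trajectory truth at both timepoints, FLAIR volumes, diffusion series
#'   with schemes, SPGR/IR-SPGR sets with protocols, masks, template prior,
#'   and a ground-truth table (class x parameter x timepoint).
#' @export
make_subject_phantom <- function(spec, subject_seed = spec$seed) {
  validate_phantom_spec(spec)
  set.seed(subject_seed)
  shp <- spec$grid_shape_structural
  vox <- spec$voxel_mm_structural
  ext <- shp * vox
  ctr <- ext / 2

  brain <- ellipsoid_mask(shp, vox, ctr, 0.46 * ext)
  wm_outer <- ellipsoid_mask(shp, vox, ctr, 0.36 * ext)
  vent <- ellipsoid_mask(shp, vox, ctr, 0.10 * ext)
  wm <- wm_outer & !vent
  nonwm <- brain & !wm

  # lesion placement inside WM, away from the WM boundary
  wm_core <- wm & !boundary_voxels(wm, 6L)
  core_idx <- which(wm_core)
  lesions <- list()
  wmh_bl <- array(FALSE, shp)
  if (spec$n_lesions > 0) {
    centers <- arrayInd(sample(core_idx, spec$n_lesions,
                               replace = spec$n_lesions > length(core_idx)),
                        shp)
    radii <- runif(spec$n_lesions, spec$lesion_radius_range_mm[1],
                   spec$lesion_radius_range_mm[2])
    for (l in seq_len(spec$n_lesions)) {
      cm <- (centers[l, ] - 0.5) * vox
      m <- sphere_mask(shp, vox, cm, radii[l]) & wm
      lesions[[l]] <- m
      wmh_bl <- wmh_bl | m
    }
  }

  # stroke lesion: one sphere in WM, stable across visits, never WMH
  stroke_ctr <- (arrayInd(sample(core_idx, 1L), shp) - 0.5) * vox
  stroke <- sphere_mask(shp, vox, as.numeric(stroke_ctr), 4) & wm
  wmh_bl <- wmh_bl & !stroke

  # assign whole lesions to progression (rim growth) or regression (rim
  # erosion); remaining lesions are stable
  n_les <- length(lesions)
  prog_rim <- array(FALSE, shp)
  reg_rim <- array(FALSE, shp)
  if (n_les > 0) {
    n_prog <- if (spec$fraction_progressing > 0)
      max(1L, round(spec$fraction_progressing * n_les)) else 0L
    n_reg <- if (spec$fraction_regressing > 0)
      max(1L, round(spec$fraction_regressing * n_les)) else 0L
    n_prog <- min(n_prog, n_les)
    n_reg <- min(n_reg, n_les - n_prog)
    ord <- sample.int(n_les)
    prog_ids <- ord[seq_len(n_prog)]
    reg_ids <- ord[n_prog + seq_len(n_reg)]
    for (l in prog_ids) {
      rim <- dilate_mask(lesions[[l]], 6L) & wm & !wmh_bl & !stroke
      prog_rim <- prog_rim | rim
    }
    for (l in reg_ids) {
      rim <- boundary_voxels(lesions[[l]] & wmh_bl, 6L) & wmh_bl
      reg_rim <- reg_rim | rim
    }
    prog_rim <- prog_rim & !reg_rim
    # de novo lesions appearing at follow-up
    if (spec$n_de_novo > 0) {
      for (k in seq_len(spec$n_de_novo)) {
        cm <- (arrayInd(sample(core_idx, 1L), shp) - 0.5) * vox
        m <- sphere_mask(shp, vox, as.numeric(cm), 1.8) & wm & !wmh_bl &
          !stroke
        prog_rim <- prog_rim | m
      }
    }
  }

  wmh_fu <- (wmh_bl & !reg_rim) | prog_rim
  if (n_les > 0 && sum(wmh_bl & wmh_fu) == 0)
    stop("change fractions leave no stable WMH voxels; rejecting spec")
  if (n_les > 0 && spec$fraction_progressing > 0 &&
      spec$fraction_regressing > 0) {
    if (sum(prog_rim) == 0 || sum(reg_rim) == 0)
      stop("phantom produced an empty change class; adjust spec")
  }

  labels_bl <- array(LABEL_BACKGROUND, shp)
  labels_bl[nonwm] <- LABEL_NONWM
  labels_bl[wm] <- LABEL_NAWM
  labels_bl[wmh_bl] <- LABEL_WMH
  labels_bl[stroke] <- LABEL_STROKE
  labels_fu <- array(LABEL_BACKGROUND, shp)
  labels_fu[nonwm] <- LABEL_NONWM
  labels_fu[wm] <- LABEL_NAWM
  labels_fu[wmh_fu] <- LABEL_WMH
  labels_fu[stroke] <- LABEL_STROKE

  traj <- array(TRAJ_NONE, shp)
  traj[labels_bl == LABEL_NAWM & labels_fu == LABEL_NAWM] <- TRAJ_STABLE_NAWM
  traj[labels_bl == LABEL_WMH & labels_fu == LABEL_WMH] <- TRAJ_STABLE_WMH
  traj[labels_bl == LABEL_NAWM & labels_fu == LABEL_WMH] <- TRAJ_PROGRESSING
  traj[labels_bl == LABEL_WMH & labels_fu == LABEL_NAWM] <- TRAJ_REGRESSING

  # subject-level parameters and effects
  cls <- draw_subject_class_params(spec)
  eff <- draw_subject_effects(spec)

  # template prior: dilated WM, smoothed, scaled to [0, 1]
  prior <- gaussian_smooth3d(dilate_mask(dilate_mask(wm, 6L), 6L) * 1, 1.5)
  prior <- prior / max(prior)

  # FLAIR contrast maps (brain-SD units) per visit
  cmap_bl <- array(0, dim = shp)
  cmap_bl[wmh_bl] <- spec$flair_contrast
  cmap_bl[stroke] <- spec$flair_contrast
  cmap_fu <- array(0, dim = shp)
  cmap_fu[wmh_fu] <- spec$flair_contrast
  cmap_fu[stroke] <- spec$flair_contrast
  flair_bl <- simulate_flair(labels_bl, cmap_bl, spec$flair_mean,
                             spec$flair_sd, spec$flair_smooth_sigma,
                             seed = subject_seed + 11L)
  flair_fu <- simulate_flair(labels_fu, cmap_fu, spec$flair_mean,
                             spec$flair_sd, spec$flair_smooth_sigma,
                             seed = subject_seed + 12L)

  # microstructure maps on the diffusion grid (NN-resampled truth labels)
  shp_d <- spec$grid_shape_diffusion
  vox_d <- spec$voxel_mm_diffusion
  traj_d <- resample_nn(traj, vox, shp_d, vox_d)
  labels_bl_d <- resample_nn(labels_bl, vox, shp_d, vox_d)
  brain_d <- labels_bl_d != LABEL_BACKGROUND
  vidx <- which(brain_d)
  nv <- length(vidx)

  set.seed(subject_seed + 21L)
  # per-voxel class row: trajectory classes 1..4 map to rows 1..4 of cls;
  # non-WM brain -> row 5; stroke -> row 6
  row_of <- integer(nv)
  tv <- traj_d[vidx]
  lv <- labels_bl_d[vidx]
  row_of[tv >= 1] <- tv[tv >= 1]
  row_of[tv == 0 & lv == LABEL_NONWM] <- 5L
  row_of[tv == 0 & lv == LABEL_STROKE] <- 6L
  row_of[row_of == 0] <- 5L  # any leftover brain voxel treated as non-WM

  vnoise <- list(ndi = rnorm(nv, 0, spec$voxel_sd),
                 odi = rnorm(nv, 0, spec$voxel_sd),
                 fwf = rnorm(nv, 0, spec$voxel_sd),
                 t1 = rnorm(nv, 0, 2 * spec$voxel_sd))
  mu_az <- runif(nv, 0, 2 * pi)
  mu_z <- runif(nv, -1, 1)
  mu <- rbind(sqrt(1 - mu_z^2) * cos(mu_az),
              sqrt(1 - mu_z^2) * sin(mu_az), mu_z)

  eff_of <- function(col) {
    e <- numeric(nv)
    sel <- tv >= 1
    e[sel] <- eff[[col]][tv[sel]]
    e
  }
  par_tp <- function(tp) {
    d <- if (tp == "bl") 0 else 1
    list(
      v_ic = clamp(cls$ndi[row_of] + vnoise$ndi + d * eff_of("d_ndi"),
                   0.02, 0.98),
      kappa = kappa_from_odi(clamp(cls$odi[row_of] + vnoise$odi +
                                     d * eff_of("d_odi"), 0.02, 0.98)),
      v_iso = clamp(cls$fwf[row_of] + vnoise$fwf + d * eff_of("d_fwf"),
                    0.005, 0.98),
      mu = mu
    )
  }
  p_bl <- par_tp("bl")
  p_fu <- par_tp("fu")
  sch_bl <- baseline_dwi_scheme()
  sch_fu <- followup_dwi_scheme()
  dwi_bl <- simulate_dwi(p_bl, sch_bl, spec$snr, seed = subject_seed + 31L)
  dwi_fu <- simulate_dwi(p_fu, sch_fu, spec$snr, seed = subject_seed + 32L)

  # T1 maps on the structural grid
  t1_of <- function(d) {
    arr <- array(0, dim = shp)
    bidx <- which(labels_bl != LABEL_BACKGROUND)
    tvs <- traj[bidx]; lvs <- labels_bl[bidx]
    rows <- integer(length(bidx))
    rows[tvs >= 1] <- tvs[tvs >= 1]
    rows[tvs == 0 & lvs == LABEL_NONWM] <- 5L
    rows[tvs == 0 & lvs == LABEL_STROKE] <- 6L
    rows[rows == 0] <- 5L
    e <- numeric(length(bidx))
    e[tvs >= 1] <- eff$d_t1[tvs[tvs >= 1]]
    arr[bidx] <- clamp(cls$t1[rows] + t1n[bidx] + d * e, 0.3, 3)
    arr
  }
  set.seed(subject_seed + 22L)
  t1n <- array(0, dim = shp)
  t1n[labels_bl != LABEL_BACKGROUND] <-
    rnorm(sum(labels_bl != LABEL_BACKGROUND), 0, 2 * spec$voxel_sd)
  t1_map_bl <- t1_of(0)
  t1_map_fu <- t1_of(1)
  m0_map <- array(0, dim = shp); m0_map[brain] <- 1000
  co <- grid_coords(shp, vox)
  b1_map <- array(1, dim = shp) +
    0.1 * outer(outer((co[[1]] - ctr[1]) / ext[1],
                      (co[[2]] - ctr[2]) / ext[2], `+`),
                (co[[3]] - ctr[3]) / ext[3], `+`)
  prot_bl <- baseline_qt1_protocol()
  prot_fu <- followup_qt1_protocol()
  spgr_bl <- simulate_spgr_ir(t1_map_bl, m0_map, b1_map, prot_bl,
                              spec$snr_qt1, seed = subject_seed + 41L)
  spgr_fu <- simulate_spgr_ir(t1_map_fu, m0_map, b1_map, prot_fu,
                              spec$snr_qt1, seed = subject_seed + 42L)

  truth <- phantom_truth_table(cls, eff)

  structure(list(
    spec = spec, subject_seed = subject_seed,
    labels_bl = labels_bl, labels_fu = labels_fu, trajectory = traj,
    flair_bl = flair_bl, flair_fu = flair_fu,
    dwi_bl = list(signals = dwi_bl, scheme = sch_bl, voxels = vidx,
                  grid_shape = shp_d, voxel_mm = vox_d),
    dwi_fu = list(signals = dwi_fu, scheme = sch_fu, voxels = vidx,
                  grid_shape = shp_d, voxel_mm = vox_d),
    spgr_ir_bl = list(signals = spgr_bl, protocol = prot_bl),
    spgr_ir_fu = list(signals = spgr_fu, protocol = prot_fu),
    t1_truth_bl = t1_map_bl, t1_truth_fu = t1_map_fu, b1_truth = b1_map,
    brain_mask = brain, wm_mask = wm, stroke_mask = stroke,
    template_prior = prior,
    voxel_mm_structural = vox, voxel_mm_diffusion = vox_d,
    class_params_subject = cls, effects_subject = eff,
    truth = truth
  ), class = "subject_phantom")
}

# ground-truth class x parameter x timepoint table; FA/MD are the
# tensor-equivalent metrics of the class-mean NODDI parameters (MD reported
# in 1e-3 mm^2/s to match the analysis tables)
phantom_truth_table <- function(cls, eff,
                                quad = watson_quadrature(),
                                scheme = baseline_dwi_scheme()) {
  rows <- list()
  for (i in seq_len(4)) {
    cl <- cls$class[i]
    for (tp in c("bl", "fu")) {
      d <- if (tp == "bl") 0 else 1
      ndi <- clamp(cls$ndi[i] + d * eff$d_ndi[i], 0.02, 0.98)
      odi <- clamp(cls$odi[i] + d * eff$d_odi[i], 0.02, 0.98)
      fwf <- clamp(cls$fwf[i] + d * eff$d_fwf[i], 0.005, 0.98)
      t1 <- cls$t1[i] + d * eff$d_t1[i]
      tm <- noddi_tensor_metrics(ndi, fwf, odi, scheme, quad)
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, timepoint = tp,
        parameter = c("FA", "MD", "T1", "NDI", "ODI", "FWF"),
        true_mean = c(tm$fa, tm$md * 1e3, t1, ndi, odi, fwf),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate a cohort of synthetic subjects
#'
#' Per-subject seeds are derived reproducibly from the master seed.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param spec a \code{phantom_spec}.
#' @param seed master seed.
#' @return list with \code{subjects} (list of \code{subject_phantom}) and
#'   \code{truth} (row-bound truth tables with a subject column).
#' @export
make_cohort <- function(n_subjects, spec, seed = spec$seed) {
  stopifnot(n_subjects >= 2)
  seeds <- cohort_subject_seeds(n_subjects, seed)
  subjects <- lapply(seq_len(n_subjects), function(i)
    make_subject_phantom(spec, seeds[i]))
  truth <- do.call(rbind, lapply(seq_len(n_subjects), function(i)
    cbind(subject = i, subjects[[i]]$truth)))
  list(subjects = subjects, truth = truth, seeds = seeds)
}

#' Reproducible per-subject seeds from a master seed
#' @param n_subjects cohort size.
#' @param seed master seed.
#' @return integer vector of n distinct seeds.
#' @export
cohort_subject_seeds <- function(n_subjects, seed) {
  set.seed(seed)
  sample.int(.Machine$integer.max %/% 2L, n_subjects)
}
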
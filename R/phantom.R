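#' Specify a synthetic lesion phantom
#'
#' Defines a mirror-symmetric digital phantom: an ellipsoidal deep-white-matter
#' compartment centered on the grid, paired midline-adjacent ventricles, and a
#' single ellipsoidal subcortical lesion confined to one hemisphere. The
#' left-right axis is axis 1 and must have an odd voxel count so that an exact
#' midline plane of symmetry exists.
#'
#' @param grid_shape Integer vector of 3 voxel counts; `grid_shape[1]` odd.
#' @param voxel_size_mm Isotropic voxel spacing in mm (default 2).
#' @param lesion_center Voxel coordinate (1-based) of the lesion centre, in one
#'   hemisphere.
#' @param lesion_radii_mm Ellipsoid semi-axes of the lesion, mm.
#' @param wm_margin_mm Gap between the grid boundary and the white-matter
#'   ellipsoid, mm.
#' @param ventricle_center_offset_mm Lateral offset of each ventricle centre
#'   from the midline, mm (the pair is mirrored).
#' @param ventricle_radii_mm Ellipsoid semi-axes of each ventricle, mm.
#' @param baseline_fw Background free-water fraction in white matter, in
#'   `[0, 1)`.
#' @param baseline_fat Background tissue fractional anisotropy, in `[0, 1]`.
#' @param baseline_md Mean diffusivity of the tissue tensor, mm^2/s.
#' @param seed Integer RNG seed associated with the phantom.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(41L, 40L, 40L),
                         voxel_size_mm = 2,
                         lesion_center = NULL,
                         lesion_radii_mm = c(6, 6, 6),
                         wm_margin_mm = 4,
                         ventricle_center_offset_mm = 6,
                         ventricle_radii_mm = c(4, 8, 6),
                         baseline_fw = 0.15,
                         baseline_fat = 0.55,
                         baseline_md = 0.7e-3,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 9L)) {
    stop("grid_shape must be 3 voxel counts >= 9", call. = FALSE)
  }
  if (grid_shape[1] %% 2L == 0L) {
    stop("grid_shape[1] (left-right axis) must be odd so a midline exists",
         call. = FALSE)
  }
  if (baseline_fw < 0 || baseline_fw >= 1) stop("baseline_fw must be in [0, 1)")
  if (baseline_fat < 0 || baseline_fat > 1) stop("baseline_fat must be in [0, 1]")
  if (is.null(lesion_center)) {
    ## centre of the left hemisphere by default
    lesion_center <- c(floor(grid_shape[1] / 2) - round(grid_shape[1] / 4),
                       round(grid_shape[2] / 2), round(grid_shape[3] / 2))
  }
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 lesion_center = lesion_center,
                 lesion_radii_mm = lesion_radii_mm,
                 wm_margin_mm = wm_margin_mm,
                 ventricle_center_offset_mm = ventricle_center_offset_mm,
                 ventricle_radii_mm = ventricle_radii_mm,
                 baseline_fw = baseline_fw, baseline_fat = baseline_fat,
                 baseline_md = baseline_md, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Specify ground-truth lesion effects on the diffusion measures
#'
#' Encodes the radially decaying, time-varying effect of the lesion on the
#' free-water fraction and tissue FA. Inside the lesion at timepoint t the
#' free-water fraction is `baseline_fw * (1 + fw_lesion_delta *
#' fw_timepoint_multipliers[t])`; in perilesional ring k the delta is
#' attenuated by `decay^k`. Defaults encode the published longitudinal
#' stroke trajectories: lesional free-water rising monotonically from +41% to
#' +251% of the contralateral value over four timepoints, tissue-FA reduction
#' deepest at the second timepoint, and a spatial decay per 2-mm ring that is
#' itself timepoint-dependent (perilesional free-water transiently recedes at
#' one month while the lesional effect keeps growing).
#'
#' @param fw_lesion_delta Relative free-water elevation inside the lesion at
#'   the reference timepoint (fraction; 0.41 = +41%).
#' @param fat_lesion_delta Relative tissue-FA change inside the lesion
#'   (negative fraction).
#' @param fw_decay_per_shell,fat_decay_per_shell Multiplicative attenuation of
#'   the respective delta per 2-mm ring; scalar, or one value per timepoint.
#'   All values in (0, 1].
#' @param fw_timepoint_multipliers,fat_timepoint_multipliers Per-timepoint
#'   scaling of the lesion deltas (length = number of timepoints).
#' @return An object of class `effect_profile`.
#' @export
effect_profile <- function(fw_lesion_delta = 0.41,
                           fat_lesion_delta = -0.343,
                           fw_decay_per_shell = c(0.665, 0.34, 0.34, 0.52),
                           fat_decay_per_shell = c(0.29, 0.55, 0.62, 0.645),
                           fw_timepoint_multipliers = c(1, 2.707, 5.073, 6.122),
                           fat_timepoint_multipliers = c(1, 1.087, 0.755, 0.534)) {
  n_tp <- length(fw_timepoint_multipliers)
  if (length(fat_timepoint_multipliers) != n_tp) {
    stop("timepoint multiplier vectors must have equal length", call. = FALSE)
  }
  fw_decay <- rep_len(fw_decay_per_shell, n_tp)
  fat_decay <- rep_len(fat_decay_per_shell, n_tp)
  if (any(fw_decay <= 0) || any(fw_decay > 1) ||
      any(fat_decay <= 0) || any(fat_decay > 1)) {
    stop("decay_per_shell values must lie in (0, 1]", call. = FALSE)
  }
  structure(list(fw_lesion_delta = fw_lesion_delta,
                 fat_lesion_delta = fat_lesion_delta,
                 fw_decay_per_shell = fw_decay,
                 fat_decay_per_shell = fat_decay,
                 fw_timepoint_multipliers = fw_timepoint_multipliers,
                 fat_timepoint_multipliers = fat_timepoint_multipliers,
                 n_timepoints = n_tp),
            class = "effect_profile")
}

## Voxelized ellipsoid: (x - c)^2 scaled by semi-axes, in mm.
ellipsoid_mask <- function(grid_shape, voxel_size, center_vox, radii_mm) {
  x <- (seq_len(grid_shape[1]) - center_vox[1]) * voxel_size / radii_mm[1]
  y <- (seq_len(grid_shape[2]) - center_vox[2]) * voxel_size / radii_mm[2]
  z <- (seq_len(grid_shape[3]) - center_vox[3]) * voxel_size / radii_mm[3]
  outer(outer(x^2, y^2, "+"), z^2, "+") <= 1
}

#' Build phantom anatomy masks
#'
#' Materializes the binary masks defined by a [phantom_spec()]: brain,
#' white matter, ventricles, lesion, plus a hemisphere label map. The
#' white-matter and ventricle masks are mirror-symmetric about the midline
#' plane by construction; the lesion lies strictly inside one hemisphere and
#' inside white matter.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom`: list with logical arrays `brain`,
#'   `wm`, `ventricles`, `lesion`, integer array `hemisphere` (-1 lesion side,
#'   +1 contralateral, 0 midline plane), `midline` index, and the spec.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape
  vox <- spec$voxel_size_mm
  mid <- (gs[1] + 1L) / 2L
  center <- (gs + 1) / 2
  brain_radii <- (gs / 2) * vox - spec$wm_margin_mm
  brain <- ellipsoid_mask(gs, vox, center, brain_radii)

  off_vox <- spec$ventricle_center_offset_mm / vox
  v1 <- ellipsoid_mask(gs, vox, c(mid - off_vox, center[2], center[3]),
                       spec$ventricle_radii_mm)
  v2 <- ellipsoid_mask(gs, vox, c(mid + off_vox, center[2], center[3]),
                       spec$ventricle_radii_mm)
  ventricles <- (v1 | v2) & brain
  wm <- brain & !ventricles

  lesion <- ellipsoid_mask(gs, vox, spec$lesion_center, spec$lesion_radii_mm)
  lx <- which(apply(lesion, 1, any))
  if (length(lx) == 0L) stop("lesion mask is empty", call. = FALSE)
  if (any(lx == mid) || (any(lx < mid) && any(lx > mid))) {
    stop("specification error: lesion touches or crosses the midline plane",
         call. = FALSE)
  }
  if (any(lesion & !wm)) {
    stop("specification error: lesion must lie inside white matter",
         call. = FALSE)
  }

  side <- if (all(lx < mid)) -1L else 1L
  hemisphere <- array(0L, gs)
  hemisphere[seq_len(mid - 1L), , ] <- side
  hemisphere[(mid + 1L):gs[1], , ] <- -side

  structure(list(brain = brain, wm = wm, ventricles = ventricles,
                 lesion = lesion, hemisphere = hemisphere,
                 midline = mid, lesion_side = side, spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("Phantom %s, voxel %g mm: brain %d, WM %d, ventricles %d, lesion %d voxels\n",
              paste(x$spec$grid_shape, collapse = "x"), x$spec$voxel_size_mm,
              sum(x$brain), sum(x$wm), sum(x$ventricles), sum(x$lesion)))
  invisible(x)
}

#' Axially symmetric tensor eigenvalues from FA and mean diffusivity
#'
#' Closed-form inversion of the fractional-anisotropy formula for a prolate
#' cylindrically symmetric tensor with eigenvalues (a, b, b): given target FA
#' `F` and mean diffusivity `m`, solves `FA = |a - b| / sqrt(a^2 + 2 b^2)`
#' subject to `(a + 2 b) / 3 = m`, taking the prolate root (`a >= b`).
#'
#' @param fa Target FA, in `[0, 1)`; vectorized.
#' @param md Mean diffusivity, mm^2/s; vectorized.
#' @return Matrix with columns `l1`, `l2` (= `l3`).
#' @export
axisym_eigenvalues <- function(fa, md) {
  if (any(fa < 0 | fa >= 1)) stop("target FA outside [0, 1)", call. = FALSE)
  f2 <- fa^2
  A <- 9 - 6 * f2
  B <- -6 * md * (3 - 2 * f2)
  C <- 9 * md^2 * (1 - f2)
  disc <- pmax(0, B^2 - 4 * A * C)
  b <- (-B - sqrt(disc)) / (2 * A)
  a <- 3 * md - 2 * b
  cbind(l1 = a, l2 = b)
}

## Smooth principal-axis field: normalized gradient of
## phi(p) = p_x^2 + 2 p_y^2 + 3 p_z^2 (mm coordinates, grid-centred).
principal_axis_field <- function(grid_shape, voxel_size) {
  center <- (grid_shape + 1) / 2
  x <- (seq_len(grid_shape[1]) - center[1]) * voxel_size
  y <- (seq_len(grid_shape[2]) - center[2]) * voxel_size
  z <- (seq_len(grid_shape[3]) - center[3]) * voxel_size
  n <- prod(grid_shape)
  gx <- 2 * rep(x, times = grid_shape[2] * grid_shape[3])
  gy <- 4 * rep(rep(y, each = grid_shape[1]), times = grid_shape[3])
  gz <- 6 * rep(z, each = grid_shape[1] * grid_shape[2])
  nrm <- sqrt(gx^2 + gy^2 + gz^2)
  zero <- nrm < 1e-12
  gx[zero] <- 1; gy[zero] <- 0; gz[zero] <- 0
  nrm[zero] <- 1
  cbind(gx / nrm, gy / nrm, gz / nrm)
}

#' Generate ground-truth free-water and tissue-tensor maps
#'
#' Applies an [effect_profile()] at one timepoint to a [build_phantom()]
#' anatomy: the free-water fraction and tissue FA are set to baseline
#' everywhere, modified inside the lesion by the lesion delta and in each
#' 1-voxel perilesional ring k (same 6-connected morphology as the analysis
#' shells) by `delta * decay^k`, restricted to the lesion hemisphere so the
#' contralateral hemisphere holds baseline values exactly. Tissue tensors are
#' cylindrically symmetric with eigenvalues hitting the target FA exactly at
#' fixed mean diffusivity, principal axis following a smooth spatial rule.
#' Ventricle voxels are assigned a free-water fraction of 0.98.
#'
#' @param phantom A [build_phantom()] result.
#' @param effect An [effect_profile()]; `NULL` for a lesion-free null phantom
#'   (baseline values everywhere).
#' @param timepoint Timepoint index (1-based) selecting the multipliers.
#' @param n_shells Number of perilesional rings carrying an attenuated effect.
#' @return An object of class `truth_maps`: list with arrays `fw`, `fat`, `md`
#'   and an `n x 6` tensor matrix `tensors` (rows indexed like the flattened
#'   grid; columns Dxx, Dyy, Dzz, Dxy, Dxz, Dyz).
#' @export
make_truth_maps <- function(phantom, effect = effect_profile(), timepoint = 1L,
                            n_shells = 8L) {
  stopifnot(inherits(phantom, "phantom"))
  gs <- phantom$spec$grid_shape
  fw <- array(phantom$spec$baseline_fw, gs)
  fat <- array(phantom$spec$baseline_fat, gs)
  md <- array(phantom$spec$baseline_md, gs)

  if (!is.null(effect)) {
    stopifnot(inherits(effect, "effect_profile"))
    tp <- as.integer(timepoint)
    if (tp < 1L || tp > effect$n_timepoints) stop("timepoint out of range")
    fw_mult <- effect$fw_timepoint_multipliers[tp]
    fat_mult <- effect$fat_timepoint_multipliers[tp]
    fw_decay <- effect$fw_decay_per_shell[tp]
    fat_decay <- effect$fat_decay_per_shell[tp]
    ipsi <- phantom$hemisphere == phantom$lesion_side

    rois <- c(list(phantom$lesion),
              build_shells(phantom$lesion, n_shells = n_shells))
    for (k in seq_along(rois)) {
      m <- rois[[k]] & ipsi & phantom$brain & !phantom$ventricles
      fw[m] <- phantom$spec$baseline_fw *
        (1 + effect$fw_lesion_delta * fw_mult * fw_decay^(k - 1L))
      fat[m] <- phantom$spec$baseline_fat *
        (1 + effect$fat_lesion_delta * fat_mult * fat_decay^(k - 1L))
    }
  }
  fw[phantom$ventricles] <- 0.98
  fat[phantom$ventricles] <- 0
  fw <- pmin(pmax(fw, 0), 0.99)
  fat <- pmin(pmax(fat, 0), 0.99)

  ev <- axisym_eigenvalues(as.vector(fat), as.vector(md))
  axis <- principal_axis_field(gs, phantom$spec$voxel_size_mm)
  ## D = (l1 - l2) v v' + l2 I
  d <- ev[, 1] - ev[, 2]
  tensors <- cbind(Dxx = d * axis[, 1]^2 + ev[, 2],
                   Dyy = d * axis[, 2]^2 + ev[, 2],
                   Dzz = d * axis[, 3]^2 + ev[, 2],
                   Dxy = d * axis[, 1] * axis[, 2],
                   Dxz = d * axis[, 1] * axis[, 3],
                   Dyz = d * axis[, 2] * axis[, 3])
  structure(list(fw = fw, fat = fat, md = md, tensors = tensors,
                 phantom = phantom, timepoint = as.integer(timepoint)),
            class = "truth_maps")
}
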
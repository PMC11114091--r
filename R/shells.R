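#' Mirror a mask across the midline plane
#'
#' Reflects a binary mask about the midline plane of the named axis. The grid
#' must have an odd voxel count on that axis so that the reflection is an
#' exact involution (for real data, supply masks already resampled to a
#' midline-symmetric grid; nonlinear registration is out of scope).
#'
#' @param mask 3-D logical/binary array.
#' @param axis Left-right axis index (default 1).
#' @return Mirrored mask, same dimensions.
#' @export
flip_mask <- function(mask, axis = 1L) {
  stopifnot_mask(mask)
  d <- dim(mask)
  if (d[axis] %% 2L == 0L) {
    stop("axis ", axis, " has even length ", d[axis],
         ": no voxel midline plane exists; supply masks on a ",
         "midline-symmetric grid (or resample with an explicit transform)",
         call. = FALSE)
  }
  idx <- rev(seq_len(d[axis]))
  if (axis == 1L) mask[idx, , ]
  else if (axis == 2L) mask[, idx, ]
  else mask[, , idx]
}

#' Remove ventricle voxels from a (flipped) lesion mask
#'
#' Set-subtracts the ventricle mask so the contralateral reference region
#' contains no cerebrospinal fluid.
#'
#' @param flipped_lesion,ventricle_mask Binary masks on one grid.
#' @return `flipped_lesion & !ventricle_mask`; warns if the result is empty.
#' @export
subtract_ventricles <- function(flipped_lesion, ventricle_mask) {
  stopifnot_mask(flipped_lesion); stopifnot_mask(ventricle_mask)
  if (!same_grid(flipped_lesion, ventricle_mask)) {
    stop("masks are on different grids", call. = FALSE)
  }
  out <- as_mask(flipped_lesion) & !as_mask(ventricle_mask)
  if (!any(out) && any(flipped_lesion)) {
    warning("flipped lesion lies entirely within the ventricle mask; ",
            "result is empty")
  }
  out
}

## One 6-connected (face-adjacent) dilation step.
dilate6 <- function(m) {
  m | shift1(m, 1L, 1L) | shift1(m, 1L, -1L) |
      shift1(m, 2L, 1L) | shift1(m, 2L, -1L) |
      shift1(m, 3L, 1L) | shift1(m, 3L, -1L)
}

## One 6-connected erosion step (outside the grid counts as background).
erode6 <- function(m) {
  m & shift1(m, 1L, 1L) & shift1(m, 1L, -1L) &
      shift1(m, 2L, 1L) & shift1(m, 2L, -1L) &
      shift1(m, 3L, 1L) & shift1(m, 3L, -1L)
}

#' Morphological erosion of a binary mask
#'
#' Applies 6-connected (face-adjacent) erosion `iterations` times; one
#' iteration removes one voxel (2 mm at the default spacing) from every
#' surface. Voxels outside the grid count as background.
#'
#' @param mask Binary 3-D mask.
#' @param iterations Non-negative integer.
#' @return Eroded mask (subset of the input); warns if empty.
#' @export
erode_mask <- function(mask, iterations = 2L) {
  stopifnot_mask(mask)
  if (iterations < 0) stop("iterations must be >= 0", call. = FALSE)
  out <- as_mask(mask)
  for (i in seq_len(iterations)) out <- erode6(out)
  if (!any(out) && any(mask)) warning("erosion produced an empty mask")
  out
}

#' Morphological dilation of a binary mask
#'
#' 6-connected counterpart of [erode_mask()]; one iteration grows the mask by
#' exactly one voxel of city-block distance.
#'
#' @inheritParams erode_mask
#' @return Dilated mask (superset of the input).
#' @export
dilate_mask <- function(mask, iterations = 1L) {
  stopifnot_mask(mask)
  if (iterations < 0) stop("iterations must be >= 0", call. = FALSE)
  out <- as_mask(mask)
  for (i in seq_len(iterations)) out <- dilate6(out)
  out
}

#' Build concentric 1-voxel tissue shells around a seed mask
#'
#' Iteratively dilates the seed with the 6-connected structuring element and
#' subtracts the previous iteration, yielding `n_shells` disjoint 1-voxel-wide
#' rings. Shell k is exactly the set of voxels at city-block (L1) distance k
#' from the seed, so with 2-mm voxels shell k spans (2k-2, 2k] mm.
#'
#' @param seed_mask Nonempty binary mask (e.g., the lesion).
#' @param n_shells Number of rings (default 8, i.e., out to 16 mm).
#' @return List of `n_shells` logical arrays, innermost first.
#' @export
build_shells <- function(seed_mask, n_shells = 8L) {
  stopifnot_mask(seed_mask)
  seed_mask <- as_mask(seed_mask)
  if (!any(seed_mask)) stop("empty seed mask", call. = FALSE)
  shells <- vector("list", n_shells)
  acc <- seed_mask
  for (k in seq_len(n_shells)) {
    nxt <- dilate6(acc)
    shells[[k]] <- nxt & !acc
    acc <- nxt
  }
  shells
}

#' Remove bilateral overlap between corresponding shells
#'
#' For each index k, the intersection of the ipsilateral and contralateral
#' shell k is removed from both, so corresponding shells never share voxels.
#' Non-corresponding indices are left untouched.
#'
#' @param ipsi_shells,contra_shells Equal-length lists of masks on one grid.
#' @return List with elements `ipsi` and `contra`.
#' @export
remove_bilateral_overlap <- function(ipsi_shells, contra_shells) {
  if (length(ipsi_shells) != length(contra_shells)) {
    stop("shell lists must have equal length", call. = FALSE)
  }
  for (k in seq_along(ipsi_shells)) {
    ov <- ipsi_shells[[k]] & contra_shells[[k]]
    ipsi_shells[[k]] <- ipsi_shells[[k]] & !ov
    contra_shells[[k]] <- contra_shells[[k]] & !ov
  }
  list(ipsi = ipsi_shells, contra = contra_shells)
}

#' Restrict shells to (eroded) white matter
#'
#' Intersects each tissue shell with a white-matter mask, limiting the
#' analysis to cerebral white matter and reducing partial-volume effects.
#'
#' @param shells List of binary masks.
#' @param eroded_wm_mask White-matter mask (typically [erode_mask()] output).
#' @return List of filtered shells; warns for each shell left empty.
#' @export
filter_with_wm <- function(shells, eroded_wm_mask) {
  stopifnot_mask(eroded_wm_mask)
  out <- lapply(shells, function(s) as_mask(s) & as_mask(eroded_wm_mask))
  n_empty <- sum(vapply(out, function(s) !any(s), logical(1)))
  if (n_empty > 0) warning(n_empty, " shell(s) empty after white-matter filtering")
  out
}

#' Construct the full lesion + perilesional shell set
#'
#' Orchestrates the region-of-interest construction in the analysis order:
#' flip the lesion to the contralateral hemisphere, subtract ventricles from
#' the flipped lesion, build `n_shells` rings around the original and flipped
#' lesion separately, remove bilateral overlap between corresponding rings,
#' and filter the rings (not the lesion) with the white matter mask eroded
#' `wm_erode_iterations` times.
#'
#' @param lesion_mask Binary lesion mask.
#' @param ventricle_mask Binary ventricle mask.
#' @param wm_mask Binary white-matter mask (uneroded).
#' @param axis Left-right axis (default 1).
#' @param n_shells Number of rings (default 8).
#' @param wm_erode_iterations Erosion iterations for the WM filter (default 2,
#'   i.e., 4 mm at 2-mm voxels).
#' @param voxel_size_mm Voxel spacing, used for shell distance labels.
#' @return An object of class `shell_set`: list with `lesion`,
#'   `flipped_lesion` (ventricle-subtracted), `ipsi_shells`, `contra_shells`
#'   (ordered lists), `labels` (location names), `wm_filtered`,
#'   `voxel_size_mm`.
#' @export
build_shellset <- function(lesion_mask, ventricle_mask, wm_mask,
                           axis = 1L, n_shells = 8L,
                           wm_erode_iterations = 2L, voxel_size_mm = 2) {
  stopifnot_mask(lesion_mask); stopifnot_mask(wm_mask)
  lesion_mask <- as_mask(lesion_mask)
  flipped <- flip_mask(lesion_mask, axis = axis)
  flipped <- subtract_ventricles(flipped, ventricle_mask)
  ipsi <- build_shells(lesion_mask, n_shells = n_shells)
  contra <- build_shells(flip_mask(lesion_mask, axis = axis), n_shells = n_shells)
  both <- remove_bilateral_overlap(ipsi, contra)
  wm_er <- erode_mask(wm_mask, iterations = wm_erode_iterations)
  ipsi <- filter_with_wm(both$ipsi, wm_er)
  contra <- filter_with_wm(both$contra, wm_er)
  labels <- c("lesion", paste0(seq_len(n_shells) * voxel_size_mm, "mm"))
  structure(list(lesion = lesion_mask, flipped_lesion = flipped,
                 ipsi_shells = ipsi, contra_shells = contra,
                 labels = labels, wm_filtered = TRUE,
                 voxel_size_mm = voxel_size_mm),
            class = "shell_set")
}

#' @export
print.shell_set <- function(x, ...) {
  cat(sprintf("Shell set: lesion %d voxels (flipped %d), %d shells, ipsi %s\n",
              sum(x$lesion), sum(x$flipped_lesion), length(x$ipsi_shells),
              paste(vapply(x$ipsi_shells, sum, numeric(1)), collapse = "/")))
  invisible(x)
}

#' Extract contralaterally normalized region means
#'
#' Computes the mean free-water and tissue-FA over the lesion and each shell
#' on both hemispheres and normalizes ipsilateral means to the corresponding
#' contralateral region: `(ipsilateral - contralateral) / contralateral`. The
#' lesion row pairs the lesion with the ventricle-subtracted flipped lesion.
#' Regions are restricted to voxels actually fitted (the fit mask), and rows
#' whose contralateral region is empty carry `NA`, never an infinity.
#'
#' @param fit A `freewater_fit` (see [fit_bitensor()]) or any list with
#'   arrays `fw_map`, `fat_map` and logical `mask`.
#' @param shellset A [build_shellset()] result.
#' @param subject,timepoint Identifiers copied into the output rows.
#' @return Data frame with one row per location x measure: columns `subject`,
#'   `timepoint`, `location`, `measure`, `ipsi_mean`, `contra_mean`,
#'   `ipsi_n`, `contra_n`, `normalized`.
#' @export
extract_measures <- function(fit, shellset, subject = NA_character_,
                             timepoint = NA_integer_) {
  stopifnot(inherits(shellset, "shell_set"))
  fitted <- as_mask(fit$mask)
  ipsi_rois <- c(list(shellset$lesion), shellset$ipsi_shells)
  contra_rois <- c(list(shellset$flipped_lesion), shellset$contra_shells)
  maps <- list(fw = fit$fw_map, fat = fit$fat_map)
  rows <- vector("list", length(ipsi_rois) * length(maps))
  r <- 0L
  for (k in seq_along(ipsi_rois)) {
    mi <- ipsi_rois[[k]] & fitted
    mc <- contra_rois[[k]] & fitted
    for (meas in names(maps)) {
      r <- r + 1L
      im <- if (any(mi)) mean(maps[[meas]][mi]) else NA_real_
      cm <- if (any(mc)) mean(maps[[meas]][mc]) else NA_real_
      norm <- if (!is.na(im) && !is.na(cm) && cm != 0) im / cm - 1 else NA_real_
      rows[[r]] <- data.frame(subject = subject, timepoint = timepoint,
                              location = shellset$labels[k], measure = meas,
                              ipsi_mean = im, contra_mean = cm,
                              ipsi_n = sum(mi), contra_n = sum(mc),
                              normalized = norm, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (any(out$ipsi_n == 0 | out$contra_n == 0)) {
    warning(sum(out$ipsi_n == 0 | out$contra_n == 0),
            " region/measure row(s) with an empty region; values set to NA")
  }
  out$location <- factor(out$location, levels = shellset$labels)
  out
}
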
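#' Default pipeline configuration
#'
#' Nested configuration driving the end-to-end synthetic run. Blocks:
#' `phantom` (grid and anatomy), `effect` (ground-truth trajectories),
#' `cohort` (subjects, retention, noise SDs), `acquisition` (directions,
#' b-value), `noise` (s0, SNR), `fit` (bi-tensor solver), `shells` (ring
#' construction) and `stats`. The default is a reduced problem size (31-voxel
#' grid, 8 subjects) chosen so a complete run stays in the minutes range on
#' one CPU; the cohort-level statistical defaults of [cohort_design()] are
#' independent of this block.
#'
#' @param seed Integer master seed; every stage derives its stream from it.
#' @return Nested list of class `run_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    phantom = list(grid_shape = c(31L, 31L, 31L), voxel_size_mm = 2,
                   wm_margin_mm = 4, baseline_fw = 0.15, baseline_fat = 0.55,
                   baseline_md = 0.7e-3),
    effect = list(fw_lesion_delta = 0.41, fat_lesion_delta = -0.343),
    cohort = list(n_subjects = 8L, retention = c(8L, 7L, 6L, 6L),
                  shrink_fraction = 0.72, lesion_meanlog = log(3),
                  lesion_sdlog = 0.4),
    acquisition = list(n_directions = 64L, b_value = 1500, n_b0 = 1L),
    noise = list(s0 = 1000, snr = 30),
    fit = list(lambda_reg = 0.1, tol = 1e-6, max_iter = 200L, d_w = 3.0e-3,
               md_tissue_ref = 0.7e-3, mask = "roi"),
    shells = list(n_shells = 8L, wm_erode_iterations = 2L),
    stats = list(alpha = 0.05, omnibus = "wald", run_lmm = TRUE)
  ), class = "run_config")
}

#' Read a pipeline configuration file
#'
#' Reads a YAML file with the [default_config()] block structure; supplied
#' keys override defaults, and unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A validated `run_config`.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user)
}

merge_config <- function(base, user, prefix = "") {
  unknown <- setdiff(names(user), names(base))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ",
         paste0(prefix, unknown, collapse = ", "), call. = FALSE)
  }
  for (k in names(user)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(user[[k]])) {
      merge_config(base[[k]], user[[k]], prefix = paste0(prefix, k, "."))
    } else user[[k]]
  }
  base
}

## NIfTI writers sharing the phantom voxel geometry.
write_map_nifti <- function(arr, path, voxel_size_mm) {
  img <- RNifti::asNifti(arr * 1)   # logical -> numeric
  RNifti::pixdim(img) <- rep(voxel_size_mm, min(length(dim(arr)), 3L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Validate co-registered pipeline inputs
#'
#' Checks that DWI and mask grids (and affines, where available) agree, that
#' masks are binary, and that the subject table carries the required schema.
#' Returns a report separating hard failures from warnings rather than
#' stopping at the first problem.
#'
#' @param dwi 4-D array or NIfTI image.
#' @param masks Named list of 3-D mask arrays/images.
#' @param table Subject/scan data frame (or `NULL` to skip table checks).
#' @return List with `ok` (logical), `failures`, `warnings` (character
#'   vectors).
#' @export
validate_inputs <- function(dwi, masks, table = NULL) {
  failures <- character()
  warns <- character()
  d <- dim(dwi)
  if (length(d) != 4L) failures <- c(failures, "DWI must be 4-D")
  grid <- d[1:3]
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!identical(dim(m)[1:3], grid)) {
      failures <- c(failures, sprintf("grid mismatch: mask '%s'", nm))
    }
    v <- unique(as.vector(as.array(m)))
    if (!all(v %in% c(0, 1, TRUE, FALSE))) {
      failures <- c(failures, sprintf("non-binary mask '%s'", nm))
    }
    if (inherits(dwi, "niftiImage") && inherits(m, "niftiImage")) {
      a1 <- RNifti::xform(dwi); a2 <- RNifti::xform(m)
      if (max(abs(a1 - a2)) > 1e-4) {
        failures <- c(failures, sprintf("affine mismatch: mask '%s'", nm))
      }
    }
  }
  if (!is.null(table)) {
    need <- c("subject_id", "timepoint", "days_since_stroke", "age", "sex",
              "lesion_volume_ml")
    miss <- setdiff(need, names(table))
    if (length(miss) > 0) {
      failures <- c(failures,
                    paste0("subject table missing column(s): ",
                           paste(miss, collapse = ", ")))
    }
    clin <- c("nihss", "uefm", "nhp", "grip_rel")
    if (!is.null(table) && length(setdiff(clin, names(table))) > 0) {
      warns <- c(warns, "clinical score column(s) absent")
    }
  }
  list(ok = length(failures) == 0L, failures = failures, warnings = warns)
}

config_design <- function(config) {
  eff <- do.call(effect_profile, config$effect)
  args <- config$cohort
  args$effect <- eff
  args$n_shells <- config$shells$n_shells
  args$baseline_fw <- config$phantom$baseline_fw
  args$baseline_fat <- config$phantom$baseline_fat
  args$seed <- child_seed(config$seed, 11L)
  do.call(cohort_design, args)
}

config_base_spec <- function(config) {
  do.call(phantom_spec, c(config$phantom, list(seed = config$seed)))
}

#' Run the complete synthetic analysis pipeline
#'
#' Executes simulate -> fit -> shells -> extract -> stats over a configured
#' synthetic cohort, writing every intermediate artifact under `out_dir`:
#' per-scan DWI (NIfTI + FSL bvals/bvecs) and masks, fitted free-water /
#' tissue-FA / mean-diffusivity / residual maps, the region-measure table and
#' the statistics tables, plus a JSON run report recording versions, seeds,
#' per-stage wall time and warning counts. A stage failure aborts with the
#' stage name; artifacts written before the failure are retained.
#'
#' @param config A `run_config` (see [default_config()], [read_config()]).
#' @param out_dir Output directory (created if needed).
#' @param keep_volumes Write per-scan NIfTI volumes (disable to save space in
#'   throwaway runs; the measure table is always written).
#' @param last_stage Stop after this stage (a prefix of the stage order), e.g.
#'   `"simulate"` to only generate the synthetic cohort volumes.
#' @return The run report, invisibly (list; also written as `report.json`).
#' @export
run_pipeline <- function(config = default_config(), out_dir,
                         keep_volumes = TRUE,
                         last_stage = c("stats", "simulate", "fit", "shells",
                                        "extract")) {
  stopifnot(inherits(config, "run_config"))
  last_stage <- match.arg(last_stage)
  stage_order <- c("simulate", "fit", "shells", "extract", "stats")
  n_stages <- match(last_stage, stage_order)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(package = "fwshells",
                 version = as.character(utils::packageVersion("fwshells")),
                 r_version = as.character(getRversion()),
                 seed = config$seed, stages = list())
  t_all <- Sys.time()

  run_stage <- function(name, fun) {
    n_warn <- 0L
    t0 <- Sys.time()
    res <- tryCatch(
      withCallingHandlers(fun(), warning = function(w) {
        n_warn <<- n_warn + 1L
        invokeRestart("muffleWarning")
      }),
      error = function(e) {
        report$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
        jsonlite::write_json(report, file.path(out_dir, "report.json"),
                             auto_unbox = TRUE, pretty = TRUE, digits = NA)
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)
      })
    report$stages[[name]] <<- list(
      status = "ok", seconds = as.numeric(Sys.time() - t0, units = "secs"),
      warnings = n_warn)
    res
  }

  ## ---- simulate ----
  sim <- run_stage("simulate", function() {
    design <- config_design(config)
    cohort <- simulate_cohort(design)
    gt <- make_gradient_table(config$acquisition$n_directions,
                              config$acquisition$b_value,
                              config$acquisition$n_b0,
                              seed = child_seed(config$seed, 21L))
    utils::write.table(cohort$scans, file.path(out_dir, "subjects.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (keep_volumes) {
      write_fsl_gradients(gt, file.path(out_dir, "bvals"),
                          file.path(out_dir, "bvecs"))
    }
    base_spec <- config_base_spec(config)
    scans <- vector("list", nrow(cohort$scans))
    for (i in seq_len(nrow(cohort$scans))) {
      sp <- cohort_phantom_spec(cohort, i, base_spec)
      ph <- build_phantom(sp)
      tp <- match(cohort$scans$timepoint[i], design$timepoints)
      truth <- make_truth_maps(ph, design$effect, timepoint = tp,
                               n_shells = config$shells$n_shells)
      dwi <- simulate_dwi(truth, gt, s0 = config$noise$s0,
                          snr = config$noise$snr, d_w = config$fit$d_w,
                          seed = sp$seed)
      sdir <- file.path(out_dir, cohort$scans$subject_id[i],
                        cohort$scans$timepoint[i])
      if (keep_volumes) {
        dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
        vx <- sp$voxel_size_mm
        write_map_nifti(dwi, file.path(sdir, "dwi.nii.gz"), vx)
        write_map_nifti(ph$lesion, file.path(sdir, "lesion_mask.nii.gz"), vx)
        write_map_nifti(ph$wm, file.path(sdir, "wm_mask.nii.gz"), vx)
        write_map_nifti(ph$ventricles,
                        file.path(sdir, "ventricle_mask.nii.gz"), vx)
      }
      scans[[i]] <- list(phantom = ph, dwi = dwi, dir = sdir)
    }
    list(cohort = cohort, design = design, gt = gt, scans = scans)
  })
  finalize <- function(value) {
    report$total_seconds <<- as.numeric(Sys.time() - t_all, units = "secs")
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(value)
  }
  if (n_stages == 1L) return(finalize(list(report = report,
                                           cohort = sim$cohort)))

  ## ---- fit ----
  fits <- run_stage("fit", function() {
    cfg <- fw_fit_config(d_w = config$fit$d_w,
                         md_tissue_ref = config$fit$md_tissue_ref,
                         lambda_reg = config$fit$lambda_reg,
                         tol = config$fit$tol, max_iter = config$fit$max_iter)
    lapply(sim$scans, function(sc) {
      ph <- sc$phantom
      mask <- if (identical(config$fit$mask, "roi")) {
        roi_union_mask(ph, config$shells$n_shells,
                       config$shells$wm_erode_iterations)
      } else ph$wm | ph$lesion
      fit <- fit_bitensor(sc$dwi, sim$gt, mask, config = cfg)
      if (keep_volumes) {
        vx <- ph$spec$voxel_size_mm
        for (nm in c("fw_map", "fat_map", "md_t_map", "residual_map")) {
          m <- fit[[nm]]; m[is.na(m)] <- 0
          write_map_nifti(m, file.path(sc$dir, paste0(nm, ".nii.gz")), vx)
        }
      }
      fit
    })
  })
  if (n_stages == 2L) return(finalize(list(report = report,
                                           cohort = sim$cohort)))

  ## ---- shells ----
  shellsets <- run_stage("shells", function() {
    lapply(sim$scans, function(sc) {
      ph <- sc$phantom
      build_shellset(ph$lesion, ph$ventricles, ph$wm,
                     n_shells = config$shells$n_shells,
                     wm_erode_iterations = config$shells$wm_erode_iterations,
                     voxel_size_mm = ph$spec$voxel_size_mm)
    })
  })
  if (n_stages == 3L) return(finalize(list(report = report,
                                           cohort = sim$cohort)))

  ## ---- extract ----
  measures <- run_stage("extract", function() {
    rows <- lapply(seq_along(sim$scans), function(i) {
      extract_measures(fits[[i]], shellsets[[i]],
                       subject = sim$cohort$scans$subject_id[i],
                       timepoint = sim$cohort$scans$timepoint[i])
    })
    tab <- do.call(rbind, rows)
    keep <- c("subject_id", "timepoint", "days_since_stroke", "age", "sex",
              "lesion_volume_ml")
    tab <- merge(tab, sim$cohort$scans[, keep],
                 by.x = c("subject", "timepoint"),
                 by.y = c("subject_id", "timepoint"), sort = FALSE)
    utils::write.table(format_measure_table(tab),
                       file.path(out_dir, "roi_measures.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    tab
  })
  if (n_stages == 4L) return(finalize(list(report = report,
                                           measures = measures,
                                           cohort = sim$cohort)))

  ## ---- stats ----
  stats_out <- run_stage("stats", function() {
    tt <- ttest_by_roi(measures)
    utils::write.table(tt, file.path(out_dir, "ttests.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    lmm <- NULL
    if (isTRUE(config$stats$run_lmm) &&
        length(unique(measures$timepoint)) >= 2L &&
        length(unique(measures$subject)) >= 3L) {
      lmm <- lapply(c(fw = "fw", fat = "fat"), function(m) {
        tryCatch(fit_longitudinal_lmm(measures, m,
                                      omnibus = config$stats$omnibus),
                 error = function(e) {
                   warning("longitudinal model (", m, ") failed: ",
                           conditionMessage(e))
                   NULL
                 })
      })
      for (m in names(lmm)) {
        if (!is.null(lmm[[m]])) {
          utils::write.table(lmm[[m]]$fixed,
                             file.path(out_dir, paste0("lmm_", m, ".tsv")),
                             sep = "\t", row.names = FALSE, quote = FALSE)
        }
      }
    }
    list(ttests = tt, lmm = lmm)
  })

  finalize(list(report = report, measures = measures, stats = stats_out,
                cohort = sim$cohort))
}

## numeric formatting for byte-stable TSV output
format_measure_table <- function(tab) {
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(x) formatC(x, digits = 10,
                                                   format = "g"))
  tab
}

## Union of all analysis regions (both hemispheres) for a restricted fit.
roi_union_mask <- function(phantom, n_shells = 8L, wm_erode_iterations = 2L) {
  les <- phantom$lesion
  fles <- flip_mask(les)
  grown <- dilate_mask(les, n_shells) | dilate_mask(fles, n_shells)
  wm_er <- erode_mask(phantom$wm, wm_erode_iterations)
  (grown & wm_er) | les | (fles & !phantom$ventricles)
}
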
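#' Design of a longitudinal lesion cohort
#'
#' Encodes the study conditions for the synthetic cohort: four imaging
#' timepoints (3-5 days, ~1, ~3 and ~12 months after the event), per-timepoint
#' retention of 26/21/19/19 scans out of 27 enrolled subjects, a 72% fraction
#' of lesions shrinking between the first and third timepoint, and the
#' ground-truth effect trajectories of [effect_profile()]. Normalized region
#' measures are modelled with three noise components: a between-subject random
#' intercept, a scan-level component shared by all regions of one session, and
#' a residual per region. Defaults for the noise components were calibrated
#' to the reported cohort uncertainties (timepoint-contrast standard errors of
#' about 0.04 for free-water and 0.007 for tissue-FA, and a lesion-level
#' between-subject spread of about 0.3).
#'
#' @param n_subjects Number of enrolled subjects.
#' @param retention Scans emitted per timepoint (missingness pattern);
#'   monotone-by-subject dropout.
#' @param timepoint_days List of `c(min, max)` day windows per timepoint.
#' @param effect An [effect_profile()].
#' @param n_shells Number of perilesional rings (locations = lesion + rings).
#' @param baseline_fw,baseline_fat Contralateral reference means.
#' @param fw_sd,fat_sd Named numeric vectors with components `between`
#'   (subject), `scan` (session) and `within` (region residual), on the
#'   normalized-measure scale. The `scan` component defaults to 0: a nonzero
#'   value induces within-session correlation across regions that the
#'   subject+location random-intercept model does not capture.
#' @param location_sd Named vector (`fw`, `fat`): SD of the location random
#'   intercept.
#' @param shrink_fraction Fraction of evaluable lesions that shrink from the
#'   first to the third timepoint.
#' @param age_mean,age_sd,female_fraction Demographics.
#' @param lesion_meanlog,lesion_sdlog Log-normal baseline lesion volume (ml).
#' @param seed Integer seed.
#' @return Object of class `cohort_design`.
#' @export
cohort_design <- function(n_subjects = 27L,
                          retention = c(26L, 21L, 19L, 19L),
                          timepoint_days = list(c(3, 5), c(30, 40),
                                                c(85, 95), c(340, 380)),
                          effect = effect_profile(),
                          n_shells = 8L,
                          baseline_fw = 0.15, baseline_fat = 0.55,
                          fw_sd = c(between = 0.15, scan = 0, within = 0.38),
                          fat_sd = c(between = 0.02, scan = 0, within = 0.066),
                          location_sd = c(fw = 0.05, fat = 0.01),
                          shrink_fraction = 0.72,
                          age_mean = 66.73, age_sd = 11.57,
                          female_fraction = 11 / 27,
                          lesion_meanlog = log(8), lesion_sdlog = 0.6,
                          seed = 1L) {
  n_tp <- length(retention)
  if (length(timepoint_days) != n_tp) {
    stop("timepoint_days and retention lengths differ", call. = FALSE)
  }
  if (any(retention > n_subjects)) {
    stop("design error: retention exceeds n_subjects", call. = FALSE)
  }
  if (effect$n_timepoints != n_tp) {
    stop("effect profile has ", effect$n_timepoints,
         " timepoints, design has ", n_tp, call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 retention = as.integer(retention),
                 timepoints = paste0("TP", seq_len(n_tp)),
                 timepoint_days = timepoint_days,
                 effect = effect, n_shells = as.integer(n_shells),
                 baseline_fw = baseline_fw, baseline_fat = baseline_fat,
                 fw_sd = fw_sd, fat_sd = fat_sd, location_sd = location_sd,
                 shrink_fraction = shrink_fraction,
                 age_mean = age_mean, age_sd = age_sd,
                 female_fraction = female_fraction,
                 lesion_meanlog = lesion_meanlog, lesion_sdlog = lesion_sdlog,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

## Expected (noise-free) normalized measure for location index k (1 = lesion,
## k = 2.. are rings) at timepoint tp.
truth_normalized <- function(effect, measure, k, tp) {
  if (measure == "fw") {
    effect$fw_lesion_delta * effect$fw_timepoint_multipliers[tp] *
      effect$fw_decay_per_shell[tp]^(k - 1)
  } else {
    effect$fat_lesion_delta * effect$fat_timepoint_multipliers[tp] *
      effect$fat_decay_per_shell[tp]^(k - 1)
  }
}

#' Simulate the cohort structure: subjects, scans, covariates
#'
#' Draws the subject table and the per-timepoint scan list implied by a
#' [cohort_design()]. Attendance is monotone-by-subject: subject s attends
#' timepoint t iff `s <= retention[t]`, so emitted scan counts match the
#' design exactly. Lesion volumes follow a log-normal baseline with a fixed
#' fraction of subjects shrinking to the third timepoint; days-since-event are
#' uniform within each timepoint window; clinical scores (NIHSS, UEFM,
#' nine-hole-peg time, relative grip force) are drawn with plausible ranges
#' and a mild dependence on lesion volume. All draws are functions of the
#' design and its seed alone.
#'
#' @param design A [cohort_design()].
#' @return Object of class `cohort`: list with data frames `subjects` and
#'   `scans` (columns subject_id, timepoint, days_since_stroke, age, sex,
#'   lesion_volume_ml, nihss, uefm, nhp, grip_rel) plus the design.
#' @export
simulate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  n <- design$n_subjects
  n_tp <- length(design$retention)
  with_seed(child_seed(design$seed, 1L), {
    ids <- sprintf("S%02d", seq_len(n))
    n_f <- round(design$female_fraction * n)
    sex <- sample(c(rep("F", n_f), rep("M", n - n_f)))
    age <- round(pmin(pmax(stats::rnorm(n, design$age_mean, design$age_sd),
                           30), 95), 1)
    vol0 <- round(stats::rlnorm(n, design$lesion_meanlog, design$lesion_sdlog), 2)

    attend <- outer(seq_len(n), design$retention, "<=")
    evaluable <- which(attend[, 1] & attend[, min(3L, n_tp)])
    n_shrink <- round(design$shrink_fraction * length(evaluable))
    shrinker <- rep(FALSE, n)
    shrinker[sample(evaluable, n_shrink)] <- TRUE
    rel3 <- ifelse(shrinker, stats::runif(n, -0.7, -0.2),
                   stats::runif(n, 0.02, 0.3))
    path <- function(tp) c(0, 0.5, 1, 1.2)[tp]

    nihss <- pmax(0, round(stats::rlnorm(n, log(4), 0.55) +
                             0.05 * (vol0 - 8)))
    uefm <- round(pmin(66, pmax(5, 66 - 2.2 * nihss -
                                  stats::rnorm(n, 0, 6))))
    nhp <- round(pmax(15, 25 + 3 * nihss + stats::rnorm(n, 0, 8)), 1)
    grip <- round(pmin(1.2, pmax(0.05, 1 - 0.06 * nihss +
                                   stats::rnorm(n, 0, 0.15))), 2)

    subjects <- data.frame(subject_id = ids, age = age, sex = sex,
                           baseline_lesion_volume_ml = vol0,
                           shrinker = shrinker, rel_change_tp3 = rel3,
                           stringsAsFactors = FALSE)

    rows <- list()
    for (tp in seq_len(n_tp)) {
      present <- which(attend[, tp])
      w <- design$timepoint_days[[tp]]
      days <- round(stats::runif(length(present), w[1], w[2]))
      vol <- round(pmax(0.05, vol0[present] *
                          (1 + rel3[present] * path(tp))), 2)
      rows[[tp]] <- data.frame(subject_id = ids[present],
                               timepoint = design$timepoints[tp],
                               days_since_stroke = days,
                               age = age[present], sex = sex[present],
                               lesion_volume_ml = vol,
                               nihss = pmax(0, nihss[present] - (tp - 1)),
                               uefm = pmin(66, uefm[present] + 3 * (tp - 1)),
                               nhp = pmax(15, nhp[present] - 2 * (tp - 1)),
                               grip_rel = pmin(1.2, grip[present] +
                                                 0.03 * (tp - 1)),
                               stringsAsFactors = FALSE)
    }
    scans <- do.call(rbind, rows)
    rownames(scans) <- NULL
    structure(list(subjects = subjects, scans = scans, design = design),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(factor(x$scans$timepoint, levels = x$design$timepoints))
  cat(sprintf("Cohort: %d subjects enrolled, scans per timepoint %s\n",
              x$design$n_subjects, paste(tab, collapse = "/")))
  invisible(x)
}

#' Simulate normalized region measures for a cohort
#'
#' Generates the region-measure table directly at the measure level from the
#' design's mixed-effects structure: for subject i, location k, timepoint t,
#' `normalized = truth(k, t) + b_i + c_k + s_it + e_ikt`, with independent
#' Gaussian subject, location, scan and residual components whose SDs come
#' from the design. The truth term is the lesion delta scaled by the
#' timepoint multiplier and attenuated per ring by the (possibly
#' timepoint-specific) decay. Ipsilateral/contralateral means are
#' reconstructed around the baseline reference so the normalization identity
#' `normalized = ipsi/contra - 1` holds exactly.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param null_effect If `TRUE`, the truth term is zero everywhere (noise-only
#'   null cohort; anatomy and covariates unchanged).
#' @return Data frame with the [extract_measures()] columns plus
#'   `days_since_stroke`, `age`, `sex`, `lesion_volume_ml`.
#' @export
simulate_cohort_measures <- function(cohort, null_effect = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  design <- cohort$design
  eff <- design$effect
  n_loc <- design$n_shells + 1L
  labels <- c("lesion", paste0(seq_len(design$n_shells) * 2, "mm"))
  scans <- cohort$scans
  n_scan <- nrow(scans)
  subj_idx <- match(scans$subject_id, cohort$subjects$subject_id)
  tp_idx <- match(scans$timepoint, design$timepoints)
  baseline <- c(fw = design$baseline_fw, fat = design$baseline_fat)
  sds <- list(fw = design$fw_sd, fat = design$fat_sd)

  with_seed(child_seed(design$seed, 2L), {
    out <- list()
    for (meas in c("fw", "fat")) {
      b_subj <- stats::rnorm(design$n_subjects, 0, sds[[meas]]["between"])
      ## location intercepts encode residual spatial structure of the effect
      ## profile; a true null carries none
      c_loc <- if (null_effect) rep(0, n_loc) else
        stats::rnorm(n_loc, 0, design$location_sd[[meas]])
      s_scan <- stats::rnorm(n_scan, 0, sds[[meas]]["scan"])
      e <- matrix(stats::rnorm(n_scan * n_loc, 0, sds[[meas]]["within"]),
                  n_scan, n_loc)
      mu <- if (null_effect) matrix(0, n_scan, n_loc) else
        t(vapply(tp_idx, function(tp)
          truth_normalized(eff, meas, seq_len(n_loc), tp), numeric(n_loc)))
      norm <- mu + b_subj[subj_idx] + s_scan +
        matrix(c_loc, n_scan, n_loc, byrow = TRUE) + e
      contra <- baseline[[meas]]
      out[[meas]] <- data.frame(
        subject = rep(scans$subject_id, times = n_loc),
        timepoint = rep(scans$timepoint, times = n_loc),
        location = rep(labels, each = n_scan),
        measure = meas,
        ipsi_mean = as.vector(contra * (1 + norm)),
        contra_mean = contra,
        ipsi_n = NA_integer_, contra_n = NA_integer_,
        normalized = as.vector(norm),
        days_since_stroke = rep(scans$days_since_stroke, times = n_loc),
        age = rep(scans$age, times = n_loc),
        sex = rep(scans$sex, times = n_loc),
        lesion_volume_ml = rep(scans$lesion_volume_ml, times = n_loc),
        stringsAsFactors = FALSE)
    }
    res <- rbind(out$fw, out$fat)
    res$location <- factor(res$location, levels = labels)
    res$timepoint <- factor(res$timepoint, levels = design$timepoints)
    rownames(res) <- NULL
    res
  })
}

#' Phantom specification for one cohort scan
#'
#' Maps a scan row of [simulate_cohort()] onto a [phantom_spec()]: the lesion
#' radius is set from the scan's lesion volume (sphere-equivalent), and the
#' phantom seed is derived from the cohort seed, subject and timepoint so
#' every scan has its own reproducible noise stream.
#'
#' @param cohort A `cohort`.
#' @param scan_row Row index into `cohort$scans`.
#' @param base_spec Template [phantom_spec()] supplying grid and baselines.
#' @return A `phantom_spec` for that scan.
#' @export
cohort_phantom_spec <- function(cohort, scan_row, base_spec = phantom_spec()) {
  stopifnot(inherits(cohort, "cohort"))
  row <- cohort$scans[scan_row, ]
  r_mm <- (3 * row$lesion_volume_ml * 1000 / (4 * pi))^(1 / 3)
  sp <- base_spec
  sp$lesion_radii_mm <- rep(max(r_mm, base_spec$voxel_size_mm), 3)
  sidx <- match(row$subject_id, cohort$subjects$subject_id)
  tpidx <- match(row$timepoint, cohort$design$timepoints)
  sp$seed <- as.integer(child_seed(cohort$design$seed,
                                   100L + sidx * 10L + tpidx) %% 2147483647)
  sp
}

#' Relative change in lesion volume
#'
#' `(V_t - V_baseline) / V_baseline` for each supplied follow-up volume.
#'
#' @param volumes Numeric vector of volumes ordered by timepoint (baseline
#'   first); `NA` for missed visits.
#' @return Numeric vector of relative changes (first element 0); `NA` where
#'   the visit is missing.
#' @export
lesion_volume_change <- function(volumes) {
  if (length(volumes) < 1L || is.na(volumes[1])) {
    stop("baseline volume is missing", call. = FALSE)
  }
  if (volumes[1] <= 0) stop("baseline volume must be positive", call. = FALSE)
  (volumes - volumes[1]) / volumes[1]
}
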
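#' One-sample t-test on normalized measures
#'
#' Two-sided test of mean zero for the normalized diffusion measure of one
#' region and timepoint, reported on the percent scale alongside Cohen's
#' d (= mean / sample SD), so that `t = d * sqrt(n)`.
#'
#' @param values Numeric vector of normalized measures (n >= 2, finite).
#' @param location,timepoint,measure Optional identifiers copied to the output.
#' @return One-row data frame: `location`, `timepoint`, `measure`, `n`,
#'   `mean_pct`, `ci_lo_pct`, `ci_hi_pct`, `t_stat`, `dof`, `p_value`,
#'   `cohens_d`.
#' @export
one_sample_t <- function(values, location = NA, timepoint = NA, measure = NA) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2L) stop("need at least 2 finite values", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0) {
    stop("degenerate sample: zero variance, no test performed", call. = FALSE)
  }
  tt <- stats::t.test(values, mu = 0)
  data.frame(location = location, timepoint = timepoint, measure = measure,
             n = n, mean_pct = 100 * mean(values),
             ci_lo_pct = 100 * tt$conf.int[1], ci_hi_pct = 100 * tt$conf.int[2],
             t_stat = unname(tt$statistic), dof = unname(tt$parameter),
             p_value = tt$p.value, cohens_d = mean(values) / s,
             stringsAsFactors = FALSE)
}

#' Per-region, per-timepoint t-test table
#'
#' Applies [one_sample_t()] to every location x timepoint x measure cell of a
#' region-measure table. No multiplicity correction is applied across the
#' grid. Degenerate cells (n < 2 or zero variance) are skipped with a warning.
#'
#' @param measures Data frame with columns `location`, `timepoint`, `measure`,
#'   `normalized` (e.g., from [extract_measures()] rows bound over subjects).
#' @return Data frame of test rows.
#' @export
ttest_by_roi <- function(measures) {
  cells <- split(measures,
                 list(measures$location, measures$timepoint, measures$measure),
                 drop = TRUE)
  rows <- lapply(cells, function(d) {
    tryCatch(one_sample_t(d$normalized, location = as.character(d$location[1]),
                          timepoint = as.character(d$timepoint[1]),
                          measure = d$measure[1]),
             error = function(e) NULL)
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped > 0) warning(skipped, " degenerate cell(s) skipped")
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Z-score within groups
#'
#' Standardizes `x` to mean 0, SD 1 within each level of `group`. Groups with
#' a single member or zero variance map to 0, keeping the covariate defined
#' for degenerate groups.
#'
#' @param x Numeric vector.
#' @param group Grouping vector of the same length.
#' @return Numeric vector of within-group z-scores.
#' @export
zscore_within_group <- function(x, group) {
  if (length(x) != length(group)) stop("lengths differ", call. = FALSE)
  out <- numeric(length(x))
  for (g in split(seq_along(x), group)) {
    s <- stats::sd(x[g])
    out[g] <- if (length(g) < 2L || is.na(s) || s == 0) 0 else
      (x[g] - mean(x[g])) / s
  }
  out
}

prepare_lmm_data <- function(table, measure) {
  d <- table[table$measure == measure, , drop = FALSE]
  need <- c("normalized", "subject", "location", "timepoint",
            "lesion_volume_ml", "age", "sex", "days_since_stroke")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  complete <- stats::complete.cases(d[, need])
  n_drop <- sum(!complete)
  if (n_drop > 0) {
    message("dropping ", n_drop, " row(s) with missing components ",
            "(missing data are never imputed)")
  }
  d <- d[complete, , drop = FALSE]
  d$timepoint <- factor(as.character(d$timepoint))
  d$location <- factor(as.character(d$location))
  d$subject <- factor(d$subject)
  d$sex <- factor(d$sex, levels = c("F", "M"))   # male as indicator level
  d$days_z <- zscore_within_group(d$days_since_stroke, d$timepoint)
  d
}

## Nakagawa-style variance partition for a lmer fit.
r2_nakagawa <- function(mod) {
  var_f <- stats::var(as.vector(lme4::getME(mod, "X") %*% lme4::fixef(mod)))
  vc <- lme4::VarCorr(mod)
  var_r <- sum(vapply(vc, function(v) v[1, 1], numeric(1)))
  var_e <- attr(vc, "sc")^2
  tot <- var_f + var_r + var_e
  c(marginal = var_f / tot, conditional = (var_f + var_r) / tot)
}

## Wald chi-square omnibus test for a factor's coefficients.
wald_omnibus <- function(mod, prefix) {
  b <- lme4::fixef(mod)
  idx <- grep(paste0("^", prefix), names(b))
  V <- as.matrix(stats::vcov(mod))[idx, idx, drop = FALSE]
  chi2 <- drop(t(b[idx]) %*% solve(V) %*% b[idx])
  df <- length(idx)
  c(chisq = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Longitudinal linear mixed-effects model of normalized measures
#'
#' Fits `normalized ~ lesion_volume_ml + age + sex + days_z + timepoint` with
#' crossed random intercepts for subject and location of measurement (REML).
#' The timepoint factor is dummy-coded with the first timepoint as reference;
#' `days_z` is days-since-event z-scored within each timepoint, controlling
#' scan-interval deviations without absorbing the timepoint effect. The
#' omnibus timepoint test is a Wald chi-square on the dummy coefficients
#' (likelihood-ratio available via `omnibus = "lrt"`); pairwise timepoint
#' contrasts use Tukey-adjusted estimated marginal means with Satterthwaite
#' degrees of freedom. Conditional and marginal R-squared follow the
#' variance-partition (Nakagawa) definition. Rows with missing components are
#' dropped (never imputed) with a message; singular fits are flagged, not
#' errors.
#'
#' @param table Region-measure table joined with covariates (see
#'   [simulate_cohort_measures()] for the expected columns).
#' @param measure `"fw"` or `"fat"`.
#' @param omnibus `"wald"` (default) or `"lrt"`.
#' @return Object of class `fw_lmm`: list with `fixed` (coefficient table),
#'   `omnibus` (chisq, df, p), `tukey` (pairwise contrast table), `r2`
#'   (marginal, conditional), `ranef_sd` (subject, location, residual),
#'   `singular`, `n_obs`, and the fitted `model`.
#' @export
fit_longitudinal_lmm <- function(table, measure = c("fw", "fat"),
                                 omnibus = c("wald", "lrt")) {
  measure <- match.arg(measure)
  omnibus <- match.arg(omnibus)
  d <- prepare_lmm_data(table, measure)
  if (nlevels(d$timepoint) < 2L) stop("need >= 2 timepoints", call. = FALSE)
  if (nlevels(d$location) < 2L) stop("need >= 2 locations", call. = FALSE)
  if (nlevels(d$subject) < 3L) stop("need >= 3 subjects", call. = FALSE)

  form <- normalized ~ lesion_volume_ml + age + sex + days_z + timepoint +
    (1 | subject) + (1 | location)
  mod <- lmerTest::lmer(form, data = d, REML = TRUE)
  singular <- lme4::isSingular(mod)
  if (singular) message("singular random-effects fit; estimates retained")

  co <- as.data.frame(stats::coef(summary(mod)))
  names(co) <- c("estimate", "se", "df", "t", "p")
  co$term <- rownames(co); rownames(co) <- NULL

  om <- if (omnibus == "wald") {
    wald_omnibus(mod, "timepoint")
  } else {
    m1 <- stats::update(mod, REML = FALSE)
    m0 <- stats::update(mod, . ~ . - timepoint, REML = FALSE)
    lrt <- stats::anova(m0, m1)
    c(chisq = lrt$Chisq[2], df = lrt$Df[2], p = lrt$`Pr(>Chisq)`[2])
  }

  emm <- emmeans::emmeans(mod, "timepoint", lmer.df = "satterthwaite")
  tk <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                        adjust = "tukey"))

  vc <- lme4::VarCorr(mod)
  ranef_sd <- c(subject = attr(vc$subject, "stddev")[[1]],
                location = attr(vc$location, "stddev")[[1]],
                residual = attr(vc, "sc"))

  structure(list(fixed = co, omnibus = om, tukey = tk, r2 = r2_nakagawa(mod),
                 ranef_sd = ranef_sd, singular = singular, n_obs = nrow(d),
                 measure = measure, model = mod),
            class = "fw_lmm")
}

#' @export
print.fw_lmm <- function(x, ...) {
  cat(sprintf("Mixed model (%s, %d obs): omnibus chi-square %.1f(%d), p %.2g; R2 cond/marg %.3f/%.3f%s\n",
              x$measure, x$n_obs, x$omnibus["chisq"], x$omnibus["df"],
              x$omnibus["p"], x$r2["conditional"], x$r2["marginal"],
              if (x$singular) " [singular]" else ""))
  invisible(x)
}

#' Cross-sectional mixed model: lesion vs shells at one timepoint
#'
#' For a single timepoint, fits `normalized ~ lesion_volume_ml + age + sex +
#' days_z + location` with a subject random intercept; the location factor is
#' dummy-coded with the lesion as reference, so each coefficient contrasts a
#' shell against the lesion. Reports the same omnibus / R-squared /
#' convergence contract as [fit_longitudinal_lmm()].
#'
#' @param table Region-measure table (one timepoint's rows are selected).
#' @param measure `"fw"` or `"fat"`.
#' @param timepoint Timepoint label to analyse.
#' @return Object of class `fw_lmm_cs`: `fixed`, `location_contrasts` (shell
#'   minus lesion), `omnibus`, `r2`, `singular`, `n_obs`, `model`.
#' @export
fit_cross_sectional_lmm <- function(table, measure = c("fw", "fat"),
                                    timepoint) {
  measure <- match.arg(measure)
  tab <- table[as.character(table$timepoint) == as.character(timepoint), ,
               drop = FALSE]
  if (nrow(tab) == 0L) stop("no rows at timepoint ", timepoint, call. = FALSE)
  d <- prepare_lmm_data(tab, measure)
  if (nlevels(d$location) < 2L) {
    stop("need >= 2 locations for the cross-sectional contrast", call. = FALSE)
  }
  d$location <- stats::relevel(d$location, ref = "lesion")
  mod <- lmerTest::lmer(normalized ~ lesion_volume_ml + age + sex + days_z +
                          location + (1 | subject), data = d, REML = TRUE)
  singular <- lme4::isSingular(mod)
  if (singular) message("singular random-effects fit; estimates retained")
  co <- as.data.frame(stats::coef(summary(mod)))
  names(co) <- c("estimate", "se", "df", "t", "p")
  co$term <- rownames(co); rownames(co) <- NULL
  lc <- co[grepl("^location", co$term), , drop = FALSE]
  lc$location <- sub("^location", "", lc$term)
  structure(list(fixed = co, location_contrasts = lc,
                 omnibus = wald_omnibus(mod, "location"),
                 r2 = r2_nakagawa(mod), singular = singular, n_obs = nrow(d),
                 measure = measure, timepoint = timepoint, model = mod),
            class = "fw_lmm_cs")
}

## All permutations of 1..n as an (n! x n) matrix (n <= 9).
perm_matrix <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- perm_matrix(n - 1L)
  m <- nrow(sub)
  out <- matrix(0L, n * m, n)
  for (pos in seq_len(n)) {
    left <- if (pos > 1L) sub[, 1:(pos - 1L), drop = FALSE] else NULL
    right <- if (pos < n) sub[, pos:(n - 1L), drop = FALSE] else NULL
    out[(pos - 1L) * m + seq_len(m), ] <- cbind(left, n, right)
  }
  out
}

#' Spearman rank correlation
#'
#' Rank correlation with midranks for ties. The p-value uses the
#' t-approximation `t = rho sqrt((n - 2) / (1 - rho^2))` by default; for
#' `n <= 9`, `exact = TRUE` enumerates the full permutation distribution of
#' rho instead (two-sided: proportion of permutations with `|rho| >=
#' |rho_observed|`).
#'
#' @param x,y Paired numeric vectors, n >= 3.
#' @param exact Exact permutation p-value; only available for n <= 9.
#' @return List with `rho`, `p_value`, `n`, `method`. A constant input vector
#'   yields `rho = NA` with a warning.
#' @export
spearman_cor <- function(x, y, exact = FALSE) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired finite values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(list(rho = NA_real_, p_value = NA_real_, n = n, method = "none"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (exact) {
    if (n > 9L) stop("exact permutation p only supported for n <= 9",
                     call. = FALSE)
    pm <- perm_matrix(n)
    ry_perm <- matrix(ry[pm], nrow(pm), n)
    rho_perm <- as.vector(stats::cor(t(ry_perm), rx))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-8)
    list(rho = rho, p_value = p, n = n, method = "exact permutation")
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
    list(rho = rho, p_value = min(p, 1), n = n, method = "t approximation")
  }
}

#' Covariate-adjusted linear regression
#'
#' Ordinary least squares of `outcome` on `predictor` plus covariates, with
#' two-sided Wald p-values; used as the robustness check behind significant
#' exploratory correlations. A rank-deficient design is an error naming the
#' collinear columns.
#'
#' @param data Data frame.
#' @param outcome,predictor Column names.
#' @param covariates Character vector of covariate column names.
#' @return List with `coefficients` (term, estimate, se, t, p), `n`, `model`.
#' @export
adjusted_regression <- function(data, outcome, predictor,
                                covariates = c("age", "sex",
                                               "baseline_lesion_volume_ml",
                                               "days_since_stroke")) {
  vars <- c(outcome, predictor, covariates)
  miss <- setdiff(vars, names(data))
  if (length(miss) > 0) stop("missing column(s): ",
                             paste(miss, collapse = ", "), call. = FALSE)
  d <- data[stats::complete.cases(data[, vars]), vars, drop = FALSE]
  form <- stats::reformulate(c(predictor, covariates), response = outcome)
  X <- stats::model.matrix(form, d)
  if (nrow(d) <= ncol(X) + 1L) stop("too few observations", call. = FALSE)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm(form, data = d)
  co <- as.data.frame(stats::coef(summary(fit)))
  names(co) <- c("estimate", "se", "t", "p")
  co$term <- rownames(co); rownames(co) <- NULL
  list(coefficients = co, n = nrow(d), model = fit)
}

#' Power of the two-sided one-sample t-test
#'
#' Noncentral-t power: with effect size d (mean / SD), n observations and
#' level alpha, the noncentrality parameter is `d sqrt(n)` and
#' `power = P(|T| > t_crit)` under the noncentral t with n - 1 degrees of
#' freedom.
#'
#' @param d Cohen's d effect size.
#' @param n Sample size (>= 2).
#' @param alpha Two-sided significance level.
#' @return Power in (0, 1).
#' @export
power_one_sample_t <- function(d, n, alpha = 0.05) {
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  df <- n - 1
  tcrit <- stats::qt(1 - alpha / 2, df)
  ncp <- d * sqrt(n)
  stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tcrit, df, ncp = ncp)
}
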
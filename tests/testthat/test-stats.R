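test_that("one-sample t-test matches hand calculation and d-t identity", {
  r <- one_sample_t(c(1, 2, 3))
  expect_equal(r$mean_pct, 200)
  expect_equal(r$t_stat, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(r$cohens_d, 2)
  expect_equal(r$t_stat, r$cohens_d * sqrt(r$n), tolerance = 1e-12)
  expect_true(r$ci_lo_pct <= r$mean_pct && r$mean_pct <= r$ci_hi_pct)
  ## symmetric values: t = 0, p = 1
  r0 <- one_sample_t(c(-2, -1, 1, 2))
  expect_equal(r0$t_stat, 0)
  expect_equal(r0$p_value, 1)
  expect_error(one_sample_t(c(3, 3, 3)), "degenerate")
  expect_error(one_sample_t(2), "at least 2")
})

test_that("the ROI t-test grid skips degenerate cells and keeps the rest", {
  tab <- data.frame(location = rep(c("lesion", "2mm"), each = 6),
                    timepoint = "TP1", measure = "fw",
                    normalized = c(rnorm(6, 0.4, 0.1), rep(0.2, 6)))
  expect_warning(out <- ttest_by_roi(tab), "degenerate")
  expect_equal(nrow(out), 1)
  expect_equal(out$location, "lesion")
})

test_that("within-group z-scoring standardizes each group independently", {
  expect_equal(zscore_within_group(c(3, 4, 5), rep("a", 3)), c(-1, 0, 1))
  expect_equal(zscore_within_group(rep(7, 4), rep("a", 4)), rep(0, 4))
  x <- c(rnorm(5, 10, 2), rnorm(7, -3, 5))
  g <- rep(c("a", "b"), c(5, 7))
  z <- zscore_within_group(x, g)
  for (gr in c("a", "b")) {
    expect_equal(mean(z[g == gr]), 0, tolerance = 1e-12)
    expect_equal(sd(z[g == gr]), 1, tolerance = 1e-12)
    expect_equal(z[g == gr], (x[g == gr] - mean(x[g == gr])) / sd(x[g == gr]))
  }
  expect_equal(zscore_within_group(5, "a"), 0)   # singleton group
})

test_that("Spearman correlation matches rank formula and permutation oracle", {
  expect_equal(spearman_cor(1:6, c(2, 4, 7, 8, 12, 20))$rho, 1)
  expect_equal(spearman_cor(1:6, -(1:6)^3)$rho, -1)
  set.seed(42)
  x <- rnorm(5); y <- rnorm(5)
  r <- spearman_cor(x, y)
  ## brute-force rank formula (no ties): 1 - 6 sum d^2 / (n(n^2-1))
  dsum <- sum((rank(x) - rank(y))^2)
  expect_equal(r$rho, 1 - 6 * dsum / (5 * 24), tolerance = 1e-12)
  ## exact permutation p equals full enumeration by an independent generator
  re <- spearman_cor(x, y, exact = TRUE)
  pm <- oracle_permutations(5)
  rho_all <- apply(pm, 1, function(p) cor(rank(x), rank(y)[p]))
  expect_equal(re$p_value, mean(abs(rho_all) >= abs(re$rho) - 1e-8),
               tolerance = 1e-12)
  ## and agrees with the reference implementation where that is exact
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = TRUE))
  expect_equal(re$p_value, ct$p.value, tolerance = 1e-12)
  ## ties: midranks
  xt <- c(1, 1, 2, 3, 4); yt <- c(2, 2, 2, 5, 9)
  expect_equal(spearman_cor(xt, yt)$rho, cor(rank(xt), rank(yt)))
  expect_warning(rc <- spearman_cor(rep(1, 5), 1:5), "constant")
  expect_true(is.na(rc$rho))
})

test_that("noncentral-t power matches quadrature and is monotone", {
  expect_equal(power_one_sample_t(0, 26), 0.05, tolerance = 1e-10)
  for (case in list(c(0.5, 26), c(0.2, 50), c(1.2, 10))) {
    expect_equal(power_one_sample_t(case[1], case[2]),
                 oracle_power_t(case[1], case[2], 0.05), tolerance = 1e-4)
  }
  p_n <- vapply(c(10, 20, 40, 80), function(n) power_one_sample_t(0.5, n),
                numeric(1))
  p_d <- vapply(c(0.1, 0.3, 0.6, 1), function(d) power_one_sample_t(d, 26),
                numeric(1))
  expect_true(all(diff(p_n) > 0))
  expect_true(all(diff(p_d) > 0))
})

test_that("adjusted regression reduces to OLS and flags collinearity", {
  set.seed(7)
  n <- 40
  d <- data.frame(age = rnorm(n, 65, 10), sex = sample(c("F", "M"), n, TRUE),
                  baseline_lesion_volume_ml = rlnorm(n, 2, 0.5),
                  days_since_stroke = runif(n, 3, 5))
  X <- model.matrix(~ age + sex + baseline_lesion_volume_ml +
                      days_since_stroke, d)
  ## predictor orthogonal to covariates: residualize against them
  raw <- rnorm(n)
  d$pred <- drop(raw - X %*% solve(crossprod(X), crossprod(X, raw)))
  d$out <- 0.8 * d$pred + rnorm(n, 0, 0.3)
  fit <- adjusted_regression(d, "out", "pred")
  slope_unadj <- coef(lm(out ~ pred, d))[["pred"]]
  expect_equal(fit$coefficients$estimate[fit$coefficients$term == "pred"],
               slope_unadj, tolerance = 1e-10)
  ## duplicated covariate: rank-deficiency error naming the column
  d$age2 <- d$age
  expect_error(adjusted_regression(d, "out", "pred",
                                   covariates = c("age", "age2")),
               "collinear.*age2")
  ## confounded design: coefficient recovered within Monte-Carlo bounds
  set.seed(8)
  reps <- vapply(1:60, function(i) {
    conf <- rnorm(n)
    dd <- data.frame(age = conf * 5 + rnorm(n, 65, 3),
                     sex = sample(c("F", "M"), n, TRUE),
                     baseline_lesion_volume_ml = rlnorm(n, 2, 0.3),
                     days_since_stroke = runif(n, 3, 5))
    dd$pred <- conf + rnorm(n, 0, 0.5)
    dd$out <- 0.6 * dd$pred + 0.4 * dd$age + rnorm(n)
    f <- adjusted_regression(dd, "out", "pred")
    f$coefficients$estimate[f$coefficients$term == "pred"]
  }, numeric(1))
  expect_lt(abs(mean(reps) - 0.6), 3 * sd(reps) / sqrt(length(reps)))
})

test_that("longitudinal mixed model partitions variance sensibly", {
  des <- cohort_design(seed = 13)
  tab <- simulate_cohort_measures(simulate_cohort(des), null_effect = TRUE)
  fit <- fit_longitudinal_lmm(tab, "fw")
  ## intercept-only truth: marginal R2 near zero, conditional above it
  expect_lt(fit$r2["marginal"], 0.05)
  expect_gt(fit$r2["conditional"], fit$r2["marginal"])
  expect_lte(fit$r2["marginal"], fit$r2["conditional"])
  expect_equal(nrow(fit$tukey), choose(4, 2))
  expect_true(all(c("subject", "location", "residual") %in%
                    names(fit$ranef_sd)))
})

test_that("longitudinal model recovers the designed trajectory pattern", {
  des <- cohort_design(seed = 3)
  tab <- simulate_cohort_measures(simulate_cohort(des))
  fit <- fit_longitudinal_lmm(tab, "fw")
  expect_lt(fit$omnibus["p"], 0.001)
  tk <- fit$tukey
  expect_gt(tk$p.value[tk$contrast == "TP1 - TP2"], 0.05)
  expect_lt(max(tk$p.value[tk$contrast != "TP1 - TP2"]), 0.05)
  ## FA-T contrasts: deepest at the second timepoint
  fitf <- fit_longitudinal_lmm(tab, "fat")
  est <- fitf$fixed$estimate
  names(est) <- fitf$fixed$term
  tps <- est[grep("^timepoint", names(est))]
  expect_equal(which.min(tps), 1L, ignore_attr = TRUE)  # TP2 dummy most negative
  ## LRT omnibus agrees qualitatively with Wald
  fit_lrt <- fit_longitudinal_lmm(tab, "fw", omnibus = "lrt")
  expect_lt(fit_lrt$omnibus["p"], 0.001)
})

test_that("cross-sectional model contrasts shells against the lesion", {
  des <- cohort_design(seed = 21)
  tab <- simulate_cohort_measures(simulate_cohort(des))
  cs <- fit_cross_sectional_lmm(tab, "fw", timepoint = "TP4")
  lc <- cs$location_contrasts
  expect_equal(nrow(lc), 8)
  ## decaying effect: the lesion-vs-16mm contrast is the largest in magnitude
  expect_equal(lc$location[which.max(abs(lc$estimate))], "16mm")
  expect_true(all(lc$estimate < 0))   # shells all below the lesion
  expect_lt(cs$omnibus["p"], 0.001)
  ## single location: precondition violation
  one <- tab[tab$location == "lesion", ]
  expect_error(fit_cross_sectional_lmm(one, "fw", timepoint = "TP4"),
               ">= 2 locations")
})
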
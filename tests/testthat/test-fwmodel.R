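test_that("predict_signal collapses correctly in the compartment limits", {
  gt <- small_gtab()
  D <- diag(c(1.4e-3, 0.4e-3, 0.4e-3))
  ## pure tissue: mono-exponential tensor decay
  a1 <- predict_signal(list(f_t = 1, D_t = D), gt)
  q <- gt$bvals * colSums(gt$bvecs * (D %*% gt$bvecs))
  expect_equal(a1, exp(-q), tolerance = 1e-12)
  ## pure free water at b = 1500: exp(-4.5) everywhere
  a0 <- predict_signal(list(f_t = 0, D_t = D, d_w = 3e-3), gt)
  expect_equal(unique(round(a0[gt$bvals > 0], 12)), round(exp(-4.5), 12))
  ## b = 0 entry is exactly 1
  expect_equal(a0[gt$bvals == 0], 1)
  expect_true(all(a1 > 0 & a1 <= 1))
})

test_that("log-linear tensor fit recovers a known tensor from clean signals", {
  gt <- small_gtab()
  D <- matrix(c(1.5e-3, 2e-4, 1e-4,
                2e-4, 6e-4, 5e-5,
                1e-4, 5e-5, 4e-4), 3, 3)
  a <- predict_signal(list(f_t = 1, D_t = D), gt)
  dwi <- array(rep(a * 800, each = 8), c(2, 2, 2, length(a)))
  fit <- fit_dti_loglinear(dwi, gt, array(TRUE, c(2, 2, 2)))
  expect_equal(unname(fit$tensors[1, ]),
               c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3]),
               tolerance = 1e-10)
  expect_equal(fit$s0[1], 800, tolerance = 1e-10)
  ## isotropic signal: all eigenvalues equal d
  d <- 9e-4
  ai <- predict_signal(list(f_t = 1, D_t = diag(rep(d, 3))), gt)
  dwi_i <- array(rep(ai * 500, each = 8), c(2, 2, 2, length(ai)))
  fi <- fit_dti_loglinear(dwi_i, gt, array(TRUE, c(2, 2, 2)))
  t6 <- fi$tensors[1, ]
  Dm <- matrix(c(t6[1], t6[4], t6[5], t6[4], t6[2], t6[6],
                 t6[5], t6[6], t6[3]), 3, 3)
  expect_equal(eigen(Dm, symmetric = TRUE)$values, rep(d, 3),
               tolerance = 1e-10)
})

test_that("tensor fit refuses fewer than 6 directions", {
  gt <- make_gradient_table(6, 1500, 1, seed = 1)
  gt$bvals <- gt$bvals[1:6]
  gt$bvecs <- gt$bvecs[, 1:6]       # 5 weighted directions remain
  dwi <- array(1, c(2, 2, 2, 6))
  expect_error(fit_dti_loglinear(dwi, gt, array(TRUE, c(2, 2, 2))),
               "at least 6")
})

test_that("free-water initialization is a clipped linear map of MD", {
  expect_equal(init_freewater(0.7e-3), 0.99)               # MD at tissue ref
  expect_equal(init_freewater(3e-3), 0.01)                 # MD at free water
  expect_equal(init_freewater((3e-3 + 0.7e-3) / 2), 0.5)   # midpoint
  md <- seq(0.5e-3, 3.5e-3, length.out = 50)
  expect_true(all(diff(init_freewater(md)) <= 0))          # monotone in MD
  expect_error(init_freewater(1e-3, d_w = 0.5e-3), "d_w > md_tissue_ref")
})

test_that("fractional anisotropy has the textbook limits", {
  expect_equal(compute_fa(diag(c(1, 1, 1))), 0)
  expect_equal(compute_fa(diag(c(1, 0, 0))), 1)
  lam <- c(1.7e-3, 0.2e-3, 0.2e-3)
  fa_expected <- sqrt(0.5 * ((lam[1] - lam[2])^2 + (lam[2] - lam[3])^2 +
                               (lam[3] - lam[1])^2) / sum(lam^2))
  expect_equal(compute_fa(diag(lam)), fa_expected, tolerance = 1e-12)
  expect_equal(round(fa_expected, 3), 0.870)
  expect_equal(compute_fa(matrix(0, 3, 3)), 0)             # all-zero tensor
  expect_message(fa_neg <- compute_fa(diag(c(1e-3, -1e-5, 2e-4))), "clamped")
  expect_gte(fa_neg, 0); expect_lte(fa_neg, 1)
  expect_error(compute_fa(matrix(1:9 * 1e-4, 3, 3)), "symmetric")
})

test_that("bi-tensor fit initialized at truth is an exact round trip", {
  ph <- build_phantom(small_spec())
  gt <- small_gtab()
  tm <- make_truth_maps(ph, effect_profile(), 1)
  dwi <- simulate_dwi(tm, gt, snr = Inf)
  mask <- ph$lesion | dilate_mask(ph$lesion, 2) & ph$wm
  vox <- which(mask)
  init <- list(f_t = 1 - tm$fw[mask], tensors = tm$tensors[vox, ])
  fit <- fit_bitensor(dwi, gt, mask, fw_fit_config(lambda_reg = 0, lambda_md = 0),
                      init = init)
  expect_lt(max(abs(fit$fw_map[mask] - tm$fw[mask])), 1e-6)
  expect_lt(max(abs(fit$fat_map[mask] - tm$fat[mask])), 1e-6)
  ## predicted signals reproduce the data (round-trip identity on signals)
  pred <- fwshells:::forward_attenuation(1 - fit$fw_map[mask], fit$tensors,
                                         gt, 3e-3)
  obs <- matrix(dwi, ncol = 65)[vox, ] / 1000
  expect_lt(max(abs(pred - obs)), 1e-6)
})

test_that("default-initialized fit recovers noiseless maps below tolerance", {
  ph <- build_phantom(small_spec())
  gt <- small_gtab()
  tm <- make_truth_maps(ph, effect_profile(), 1)
  dwi <- simulate_dwi(tm, gt, snr = Inf)
  fit <- fit_bitensor(dwi, gt, ph$wm, fw_fit_config(lambda_reg = 0,
                                                    lambda_md = 0))
  expect_lt(median(abs(fit$fw_map[ph$wm] - tm$fw[ph$wm])), 0.01)
})

test_that("emitted maps respect ranges and mask boundaries", {
  ph <- build_phantom(small_spec())
  gt <- small_gtab()
  tm <- make_truth_maps(ph, effect_profile(), 2)
  dwi <- simulate_dwi(tm, gt, snr = 20, seed = 3)
  fit <- fit_bitensor(dwi, gt, ph$wm)
  inm <- ph$wm
  expect_true(all(fit$fw_map[inm] >= 0 & fit$fw_map[inm] <= 1))
  expect_true(all(fit$fat_map[inm] >= 0 & fit$fat_map[inm] <= 1))
  expect_true(all(fit$residual_map[inm] >= 0))
  expect_true(all(is.na(fit$fw_map[!inm])))
  expect_true(all(is.na(fit$fat_map[!inm])))
})

test_that("free-water error shrinks with SNR and regularization helps at low SNR", {
  ph <- build_phantom(small_spec())
  gt <- small_gtab()
  tm <- make_truth_maps(ph, effect_profile(), 1)
  wm <- ph$wm
  rmse <- vapply(c(10, 20, Inf), function(snr) {
    dwi <- simulate_dwi(tm, gt, snr = snr, seed = 5)
    fit <- fit_bitensor(dwi, gt, wm)
    sqrt(mean((fit$fw_map[wm] - tm$fw[wm])^2))
  }, numeric(1))
  expect_true(all(diff(rmse) <= 0))        # non-increasing in SNR
  ## degeneracy at snr 10 without penalties: fw and MD errors trade off
  dwi10 <- simulate_dwi(tm, gt, snr = 10, seed = 6)
  f_un <- fit_bitensor(dwi10, gt, wm, fw_fit_config(lambda_reg = 0,
                                                    lambda_md = 0))
  f_re <- fit_bitensor(dwi10, gt, wm)
  e_fw <- f_un$fw_map[wm] - tm$fw[wm]
  e_md <- f_un$md_t_map[wm] - tm$md[wm]
  ellipse <- stats::cov(cbind(e_fw, e_md))  # the reported error ellipse
  expect_gt(abs(stats::cor(e_fw, e_md)), 0.5)
  expect_lt(sqrt(mean((f_re$fw_map[wm] - tm$fw[wm])^2)),
            sqrt(mean(e_fw^2)))
  expect_gt(ellipse[1, 1], 0)
})
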
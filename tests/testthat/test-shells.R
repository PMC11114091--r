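test_that("mask flipping is a volume-preserving involution", {
  m <- array(FALSE, c(9, 6, 6))
  m[3, 2, 5] <- TRUE
  f <- flip_mask(m)
  expect_equal(unname(which(f, arr.ind = TRUE)[1, ]), c(7, 2, 5))
  expect_identical(flip_mask(f), m)
  expect_equal(sum(f), sum(m))
  expect_error(flip_mask(array(FALSE, c(8, 6, 6))), "even length")
})

test_that("ventricle subtraction is plain set arithmetic", {
  a <- array(FALSE, c(5, 5, 5)); a[1:2, 1, 1] <- TRUE
  b <- array(FALSE, c(5, 5, 5)); b[4:5, 5, 5] <- TRUE
  expect_identical(subtract_ventricles(a, b), a)         # disjoint
  expect_warning(out <- subtract_ventricles(a, a), "empty")
  expect_false(any(out))                                 # fully inside
  les <- array(FALSE, c(5, 5, 5)); les[1:10] <- TRUE
  ven <- array(FALSE, c(5, 5, 5)); ven[8:10] <- TRUE
  expect_equal(sum(subtract_ventricles(les, ven)), 7)    # 10 - 3 overlap
})

test_that("6-connected erosion matches the brute-force oracle", {
  cube <- array(FALSE, c(9, 9, 9)); cube[3:7, 3:7, 3:7] <- TRUE
  e2 <- erode_mask(cube, 2)
  expect_equal(which(e2), which(array(seq_len(9^3), c(9, 9, 9)) ==
                                  (5 - 1) * 81 + (5 - 1) * 9 + 5))
  expect_equal(sum(e2), 1)                               # 5^3 -> centre voxel
  expect_identical(erode_mask(cube, 0), cube)            # identity
  sheet <- array(FALSE, c(7, 7, 7)); sheet[4, , ] <- TRUE
  expect_warning(e <- erode_mask(sheet, 1), "empty")
  expect_false(any(e))                                   # thin sheet dies
  ## random blobs against the oracle
  set.seed(4)
  for (i in 1:5) {
    m <- random_seed_mask(c(10, 10, 10), 4)
    expect_identical(erode_mask(dilate_mask(m, 1), 1),
                     oracle_erode6(dilate_mask(m, 1)))
  }
})

test_that("shells equal city-block distance strata", {
  ## single voxel: 6 face neighbours, then the 18 voxels at L1 distance 2
  m <- array(FALSE, c(11, 11, 11)); m[6, 6, 6] <- TRUE
  sh <- build_shells(m, 3)
  expect_equal(vapply(sh, sum, numeric(1)), c(6, 18, 38))  # 4k^2 + 2
  dist <- oracle_l1_distance(m)
  for (k in 1:3) expect_identical(sh[[k]], dist == k)
  expect_error(build_shells(array(FALSE, c(3, 3, 3))), "empty seed")
})

test_that("shell stratification matches the distance-transform oracle on random seeds", {
  set.seed(11)
  for (i in 1:10) {
    gs <- c(sample(c(9L, 13L), 1), sample(10:14, 1), sample(10:14, 1))
    m <- random_seed_mask(gs, 3)
    sh <- build_shells(m, 4)
    dist <- oracle_l1_distance(m)
    for (k in 1:4) expect_identical(sh[[k]], dist == k)
    ## conservation: seed + shells = dilate^4(seed)
    un <- m
    for (s in sh) {
      expect_false(any(un & s))   # disjoint
      un <- un | s
    }
    expect_identical(un, dilate_mask(m, 4))
  }
})

test_that("bilateral overlap is removed symmetrically", {
  a <- array(FALSE, c(7, 7, 7)); a[2:3, 4, 4] <- TRUE
  b <- array(FALSE, c(7, 7, 7)); b[5:6, 4, 4] <- TRUE
  out <- remove_bilateral_overlap(list(a), list(b))
  expect_identical(out$ipsi[[1]], a)                     # disjoint: unchanged
  out2 <- remove_bilateral_overlap(list(a), list(a))
  expect_false(any(out2$ipsi[[1]]) || any(out2$contra[[1]]))  # identical: empty
  c1 <- array(FALSE, c(7, 7, 7)); c1[3:5, 4, 4] <- TRUE
  out3 <- remove_bilateral_overlap(list(a), list(c1))
  inter <- a & c1
  expect_identical(out3$ipsi[[1]], a & !inter)
  expect_identical(out3$contra[[1]], c1 & !inter)
})

test_that("white-matter filtering intersects shells with the WM mask", {
  m <- array(FALSE, c(9, 9, 9)); m[5, 5, 5] <- TRUE
  sh <- build_shells(m, 2)
  full <- array(TRUE, c(9, 9, 9))
  expect_identical(filter_with_wm(sh, full), sh)
  expect_warning(empty <- filter_with_wm(sh, array(FALSE, c(9, 9, 9))),
                 "empty")
  expect_false(any(vapply(empty, any, logical(1))))
  ph <- build_phantom(small_spec())
  shp <- build_shells(ph$lesion, 3)
  filt <- filter_with_wm(shp, ph$wm)
  for (k in 1:3) expect_equal(sum(filt[[k]]), sum(shp[[k]] & ph$wm))
})

test_that("normalization is (ipsi - contra)/contra, with NA for empty regions", {
  ph <- build_phantom(small_spec())
  ss <- build_shellset(ph$lesion, ph$ventricles, ph$wm)
  ## synthetic maps: ipsi value 1.406 vs contra 1.0 in every region
  fw <- array(1, dim(ph$brain))
  fw[ph$hemisphere == ph$lesion_side] <- 1.406
  fit <- list(fw_map = fw, fat_map = fw, mask = array(TRUE, dim(ph$brain)))
  m <- extract_measures(fit, ss)
  expect_equal(m$normalized[m$location == "lesion" & m$measure == "fw"], 0.406,
               tolerance = 1e-12)
  expect_true(all(abs(m$normalized - (m$ipsi_mean / m$contra_mean - 1)) < 1e-12))
  ## identical hemispheres: exact zero everywhere
  fit0 <- list(fw_map = array(2, dim(ph$brain)), fat_map = array(2, dim(ph$brain)),
               mask = array(TRUE, dim(ph$brain)))
  m0 <- extract_measures(fit0, ss)
  expect_true(all(m0$normalized == 0))
  ## empty contralateral region -> NA, not infinity
  fitNA <- list(fw_map = fw, fat_map = fw,
                mask = ph$hemisphere == ph$lesion_side)
  expect_warning(mNA <- extract_measures(fitNA, ss), "empty")
  expect_true(all(is.na(mNA$normalized[mNA$contra_n == 0])))
  expect_false(any(is.infinite(mNA$normalized)))
})

test_that("shell set construction keeps the lesion unfiltered and shells in WM", {
  ph <- build_phantom(small_spec())
  ss <- build_shellset(ph$lesion, ph$ventricles, ph$wm)
  expect_identical(ss$lesion, ph$lesion)                 # lesion untouched
  expect_false(any(ss$flipped_lesion & ph$ventricles))   # CSF removed
  wm_er <- erode_mask(ph$wm, 2)
  for (k in 1:8) {
    expect_false(any(ss$ipsi_shells[[k]] & !wm_er))
    expect_false(any(ss$ipsi_shells[[k]] & ss$contra_shells[[k]]))
  }
  expect_equal(ss$labels, c("lesion", paste0(2 * 1:8, "mm")))
})

test_that("effect phantom yields monotonically decaying normalized free-water", {
  ph <- build_phantom(effect_spec())
  tm <- make_truth_maps(ph, effect_profile(), 1)
  ss <- build_shellset(ph$lesion, ph$ventricles, ph$wm)
  fit <- list(fw_map = tm$fw, fat_map = tm$fat, mask = ph$brain)
  m <- extract_measures(fit, ss)
  fw <- m$normalized[m$measure == "fw"]
  expect_true(all(diff(abs(fw)) <= 1e-12))
  expect_equal(fw[1], 0.41, tolerance = 1e-10)   # lesion: exact truth
})
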
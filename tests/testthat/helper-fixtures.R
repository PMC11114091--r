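## Shared fixtures and independent oracles. Oracles are deliberately written
## with different algorithms than the implementation they check.

## Small phantom that fits a lesion + 8 shells on a 21x20x20 grid.
small_spec <- function(seed = 1L) {
  phantom_spec(grid_shape = c(21L, 20L, 20L),
               lesion_radii_mm = c(4, 4, 4), lesion_center = c(5, 10, 10),
               ventricle_center_offset_mm = 4,
               ventricle_radii_mm = c(3, 6, 5), seed = seed)
}

small_gtab <- function(n = 64L, seed = 7L) make_gradient_table(n, 1500, 1L, seed = seed)

## Wider phantom whose 8 shells stay inside the lesion hemisphere (lesion
## surface to midline distance = 8 voxels), so shell means carry the exact
## geometric decay.
effect_spec <- function(seed = 1L) {
  phantom_spec(grid_shape = c(33L, 26L, 26L),
               lesion_radii_mm = c(4, 4, 4), lesion_center = c(7, 13, 13),
               ventricle_center_offset_mm = 4,
               ventricle_radii_mm = c(3, 6, 5), seed = seed)
}

## Brute-force ellipsoid voxel scan (independent of ellipsoid_mask).
oracle_ellipsoid_count <- function(grid_shape, voxel, center, radii) {
  count <- 0L
  for (i in seq_len(grid_shape[1])) for (j in seq_len(grid_shape[2]))
    for (k in seq_len(grid_shape[3])) {
      v <- ((i - center[1]) * voxel / radii[1])^2 +
        ((j - center[2]) * voxel / radii[2])^2 +
        ((k - center[3]) * voxel / radii[3])^2
      if (v <= 1) count <- count + 1L
    }
  count
}

## City-block (L1) distance of every voxel to the nearest seed voxel,
## brute force over seed voxels.
oracle_l1_distance <- function(seed_mask) {
  d <- dim(seed_mask)
  seeds <- which(seed_mask, arr.ind = TRUE)
  co <- arrayInd(seq_len(prod(d)), d)
  dist <- array(Inf, d)
  for (s in seq_len(nrow(seeds))) {
    ds <- abs(co[, 1] - seeds[s, 1]) + abs(co[, 2] - seeds[s, 2]) +
      abs(co[, 3] - seeds[s, 3])
    dist <- pmin(dist, array(ds, d))
  }
  dist
}

## Brute-force 6-connected erosion (per-voxel neighbour check).
oracle_erode6 <- function(m) {
  d <- dim(m)
  out <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!m[i, j, k]) next
    nb <- c(
      if (i > 1) m[i - 1, j, k] else FALSE,
      if (i < d[1]) m[i + 1, j, k] else FALSE,
      if (j > 1) m[i, j - 1, k] else FALSE,
      if (j < d[2]) m[i, j + 1, k] else FALSE,
      if (k > 1) m[i, j, k - 1] else FALSE,
      if (k < d[3]) m[i, j, k + 1] else FALSE)
    out[i, j, k] <- all(nb)
  }
  out
}

## Exhaustive permutation generator (independent of perm_matrix): enumerate
## all n^n index tuples and keep the bijections. Fine for n <= 6.
oracle_permutations <- function(n) {
  g <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  dimnames(g) <- NULL
  g[apply(g, 1, function(r) length(unique(r)) == n), , drop = FALSE]
}

## Noncentral-t tail probability by integrating over the chi-square variable
## (independent of pt's noncentral algorithm): T = (Z + ncp)/sqrt(V/df).
oracle_power_t <- function(d, n, alpha) {
  df <- n - 1
  tcrit <- qt(1 - alpha / 2, df)
  ncp <- d * sqrt(n)
  integrand <- function(x) {
    s <- sqrt(x / df)
    (pnorm(ncp - tcrit * s) + pnorm(-tcrit * s - ncp)) * dchisq(x, df)
  }
  integrate(integrand, 0, Inf, rel.tol = 1e-10)$value
}

## Random blob seed mask on a small grid (for shell-geometry checks).
random_seed_mask <- function(grid_shape, n_points = 3L) {
  m <- array(FALSE, grid_shape)
  pts <- cbind(sample(2:(grid_shape[1] - 1), n_points, replace = TRUE),
               sample(2:(grid_shape[2] - 1), n_points, replace = TRUE),
               sample(2:(grid_shape[3] - 1), n_points, replace = TRUE))
  m[pts] <- TRUE
  dilate_mask(m, sample(0:1, 1))
}
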
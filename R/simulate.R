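#' Simulate a single-shell DWI volume from ground-truth maps
#'
#' Runs the two-compartment model forward over a [make_truth_maps()] result:
#' per voxel and direction the noiseless attenuation is
#' `A = f_t exp(-b g' D_t g) + (1 - f_t) exp(-b d_w)`, scaled by `s0` inside
#' the brain (zero outside). Rician noise is applied as the magnitude of
#' `(A s0 + n1, n2)` with independent Gaussian `n1, n2` of standard deviation
#' `sigma = s0 / snr`, the noise distribution of magnitude MR data.
#'
#' @param truth A `truth_maps` object.
#' @param gradient_table A `gradient_table`.
#' @param s0 Unweighted signal amplitude (arbitrary units).
#' @param snr Signal-to-noise ratio relative to `s0`; `Inf` disables noise.
#' @param d_w Free-water diffusivity, mm^2/s.
#' @param seed Integer seed (noise is deterministic given the seed).
#' @return 4-D array (x, y, z, volume) of signals.
#' @export
simulate_dwi <- function(truth, gradient_table, s0 = 1000, snr = 30,
                         d_w = 3.0e-3, seed = 1L) {
  stopifnot(inherits(truth, "truth_maps"))
  gt <- validate_gradient_table(gradient_table)
  if (!(snr > 0)) stop("snr must be positive (use Inf for noiseless)",
                       call. = FALSE)
  gs <- dim(truth$fw)
  brain <- truth$phantom$brain
  vox <- which(brain)
  f_t <- 1 - truth$fw[vox]
  A <- forward_attenuation(f_t, truth$tensors[vox, , drop = FALSE], gt, d_w)
  nvol <- length(gt$bvals)
  S <- array(0, c(gs, nvol))
  flat <- matrix(0, prod(gs), nvol)
  flat[vox, ] <- A * s0
  if (is.finite(snr)) {
    ## noise covers the whole field of view: background voxels end up
    ## Rayleigh-distributed, as in real magnitude images
    sigma <- s0 / snr
    flat <- with_seed(seed, {
      n1 <- matrix(stats::rnorm(length(flat), sd = sigma), nrow(flat))
      n2 <- matrix(stats::rnorm(length(flat), sd = sigma), nrow(flat))
      sqrt((flat + n1)^2 + n2^2)
    })
  }
  S[] <- flat
  S
}
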
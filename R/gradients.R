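#' Build a single-shell diffusion gradient table
#'
#' Constructs a gradient table with `n_b0` unweighted volumes followed by
#' `n_directions` diffusion-weighted volumes at a single b-value. Directions
#' are placed on a spherical-Fibonacci lattice (approximately uniform on the
#' sphere) and then rotated by a seeded random 3-D rotation, so tables are
#' deterministic given the seed while different seeds decorrelate direction
#' sets.
#'
#' @param n_directions Number of diffusion-weighted directions (>= 6, the
#'   identifiability bound of the diffusion tensor).
#' @param b_value Diffusion weighting in s/mm^2.
#' @param n_b0 Number of b = 0 volumes (zero gradient vector).
#' @param seed Integer seed for the rotation.
#' @return An object of class `gradient_table`: a list with `bvals`
#'   (numeric vector, length `n_b0 + n_directions`) and `bvecs`
#'   (3 x n matrix of unit column vectors; zero columns for b = 0).
#' @examples
#' gt <- make_gradient_table(64, 1500, n_b0 = 1, seed = 7)
#' length(gt$bvals)  # 65
#' @export
make_gradient_table <- function(n_directions, b_value, n_b0 = 1L, seed = 1L) {
  if (n_directions < 6L) {
    stop("invalid acquisition: at least 6 non-collinear directions are ",
         "required to identify a diffusion tensor", call. = FALSE)
  }
  if (b_value <= 0) stop("b_value must be positive", call. = FALSE)
  n <- as.integer(n_directions)
  i <- seq_len(n) - 1L
  golden <- pi * (3 - sqrt(5))
  z <- 1 - (2 * i + 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * golden
  dirs <- rbind(r * cos(phi), r * sin(phi), z)
  rot <- with_seed(seed, random_rotation())
  dirs <- rot %*% dirs
  dirs <- sweep(dirs, 2, sqrt(colSums(dirs^2)), "/")
  ## non-collinearity audit (parallel or antiparallel)
  dots <- abs(crossprod(dirs))
  diag(dots) <- 0
  if (max(dots) > 1 - 1e-6) {
    stop("invalid acquisition: collinear gradient directions", call. = FALSE)
  }
  bvals <- c(rep(0, n_b0), rep(b_value, n))
  bvecs <- cbind(matrix(0, 3, n_b0), dirs)
  structure(list(bvals = bvals, bvecs = bvecs), class = "gradient_table")
}

random_rotation <- function() {
  ## QR of a Gaussian matrix, sign-fixed to a proper rotation
  qr_d <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_d)
  q <- q %*% diag(sign(diag(qr.R(qr_d))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' @export
print.gradient_table <- function(x, ...) {
  nb0 <- sum(x$bvals == 0)
  cat(sprintf("Gradient table: %d volumes (%d b=0, %d weighted, b = %s s/mm^2)\n",
              length(x$bvals), nb0, length(x$bvals) - nb0,
              paste(unique(x$bvals[x$bvals > 0]), collapse = ", ")))
  invisible(x)
}

validate_gradient_table <- function(gt) {
  if (!inherits(gt, "gradient_table")) stop("not a gradient_table", call. = FALSE)
  if (length(gt$bvals) != ncol(gt$bvecs)) {
    stop("format error: bvals and bvecs lengths differ", call. = FALSE)
  }
  nz <- gt$bvals > 0
  norms <- sqrt(colSums(gt$bvecs[, nz, drop = FALSE]^2))
  if (any(abs(norms - 1) > 1e-6)) {
    stop("nonzero-b directions must have unit norm", call. = FALSE)
  }
  invisible(gt)
}

#' Read an FSL-dialect gradient table
#'
#' Reads whitespace-separated `bvals` (one row) and `bvecs` (three rows,
#' x/y/z) files as written by FSL and most diffusion pipelines. Nonzero
#' direction vectors whose norm deviates from 1 by more than 1e-3 are
#' re-normalized with a warning.
#'
#' @param bval_path,bvec_path Paths to the two text files.
#' @return A `gradient_table`.
#' @export
read_fsl_gradients <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  bv <- as.matrix(utils::read.table(bvec_path))
  dimnames(bv) <- NULL
  if (nrow(bv) != 3L) {
    stop("format error: bvec file must have exactly 3 rows, found ",
         nrow(bv), call. = FALSE)
  }
  if (length(bvals) != ncol(bv)) {
    stop("format error: bvals (", length(bvals), ") and bvecs (", ncol(bv),
         ") volume counts differ", call. = FALSE)
  }
  nz <- bvals > 0
  norms <- sqrt(colSums(bv[, nz, drop = FALSE]^2))
  if (any(abs(norms - 1) > 1e-3)) {
    warning("re-normalizing ", sum(abs(norms - 1) > 1e-3),
            " gradient vector(s) with non-unit norm")
  }
  bv[, nz] <- sweep(bv[, nz, drop = FALSE], 2, norms, "/")
  structure(list(bvals = bvals, bvecs = bv), class = "gradient_table")
}

#' Write an FSL-dialect gradient table
#'
#' @param gt A `gradient_table`.
#' @param bval_path,bvec_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_fsl_gradients <- function(gt, bval_path, bvec_path) {
  validate_gradient_table(gt)
  writeLines(paste(format(gt$bvals, scientific = FALSE, trim = TRUE),
                   collapse = " "), bval_path)
  writeLines(apply(gt$bvecs, 1, function(r)
    paste(format(r, digits = 15, scientific = FALSE, trim = TRUE),
          collapse = " ")), bvec_path)
  invisible(c(bval_path, bvec_path))
}
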
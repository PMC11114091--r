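## Two-compartment (free-water elimination) model for single-shell DWI.
##
## Signal model per voxel and direction i:
##   A_i = f_t * exp(-b_i g_i' D_t g_i) + (1 - f_t) * exp(-b_i d_w)
## with f_t the tissue volume fraction (free-water fraction fw = 1 - f_t),
## D_t the tissue diffusion tensor and d_w the fixed diffusivity of free
## water at body temperature.

#' Configuration for the bi-tensor fit
#'
#' @param d_w Free-water diffusivity, mm^2/s (3.0e-3: isotropic water at
#'   37 degrees C).
#' @param md_tissue_ref Reference healthy-tissue mean diffusivity used by the
#'   free-water initialization, mm^2/s.
#' @param eps Box-constraint margin for the tissue fraction: f_t is kept in
#'   `[eps, 1 - eps]`.
#' @param lambda_reg Weight of the spatial regularization penalty pulling each
#'   voxel's f_t toward the 6-neighbour mean of the previous outer iterate
#'   (scaled by the number of volumes). 0 disables it.
#' @param lambda_md Weight of the soft tissue mean-diffusivity prior anchoring
#'   `tr(D_t)/3` to `md_tissue_ref`; this is what makes the free-water
#'   fraction identifiable on single-shell data. 0 disables it.
#' @param n_outer Number of outer (fit + anchor update) cycles when
#'   `lambda_reg > 0`.
#' @param tol Convergence tolerance on the maximum absolute parameter change.
#' @param ftol Relative cost-decrease tolerance: an accepted step whose
#'   sum-of-squares improvement falls below `ftol * cost` also counts as
#'   converged (standard secondary stopping rule for least squares).
#' @param max_iter Maximum Levenberg-Marquardt iterations per (outer) fit.
#' @param signal_floor Attenuations at or below this value are clamped to it
#'   (nonpositive raw signals; count is recorded on the fit object).
#' @return List of class `fw_fit_config`.
#' @export
fw_fit_config <- function(d_w = 3.0e-3, md_tissue_ref = 0.7e-3, eps = 0.01,
                          lambda_reg = 0.1, lambda_md = 0.1, n_outer = 3L,
                          tol = 1e-6, ftol = 1e-10, max_iter = 200L,
                          signal_floor = 1e-4) {
  stopifnot(d_w > md_tissue_ref, md_tissue_ref > 0, eps > 0, eps < 0.5)
  structure(list(d_w = d_w, md_tissue_ref = md_tissue_ref, eps = eps,
                 lambda_reg = lambda_reg, lambda_md = lambda_md,
                 n_outer = as.integer(n_outer),
                 tol = tol, ftol = ftol, max_iter = as.integer(max_iter),
                 signal_floor = signal_floor),
            class = "fw_fit_config")
}

## nd x 6 quadratic-form design for tensor fitting: q_i = b_i * X_i . D6
tensor_design <- function(gt) {
  g <- gt$bvecs
  cbind(g[1, ]^2, g[2, ]^2, g[3, ]^2,
        2 * g[1, ] * g[2, ], 2 * g[1, ] * g[3, ], 2 * g[2, ] * g[3, ]) * gt$bvals
}

## Batch forward model: f (n), tensors (n x 6) -> attenuations (n x nd)
forward_attenuation <- function(f, tensors, gt, d_w) {
  q <- tensors %*% t(tensor_design(gt))
  ciso <- exp(-gt$bvals * d_w)
  f * exp(-q) + outer(1 - f, ciso)
}

#' Predict bi-tensor signal attenuations for one voxel
#'
#' Evaluates the two-compartment forward model
#' `A_i = f_t exp(-b_i g_i' D_t g_i) + (1 - f_t) exp(-b_i d_w)` for every
#' volume of a gradient table.
#'
#' @param params List with `f_t` (tissue fraction in `[0, 1]`), `D_t`
#'   (symmetric 3x3 tensor, mm^2/s) and optionally `d_w` (default 3.0e-3).
#' @param gradient_table A [make_gradient_table()] object.
#' @return Numeric vector of attenuations in (0, 1] for PSD `D_t`.
#' @export
predict_signal <- function(params, gradient_table) {
  stopifnot(is.list(params), !is.null(params$f_t), !is.null(params$D_t))
  d_w <- params$d_w %||% 3.0e-3
  D <- params$D_t
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-10))) {
    stop("D_t must be symmetric", call. = FALSE)
  }
  t6 <- matrix(c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3]), 1)
  drop(forward_attenuation(params$f_t, t6, gradient_table, d_w))
}

#' Log-linear diffusion tensor fit (initialization stage)
#'
#' Ordinary least squares on the log-attenuations, the classical DTI fit.
#' `s0` is the geometric mean of the b = 0 volumes; attenuations are
#' `S / s0` with nonpositive values clamped to `signal_floor`.
#'
#' @param dwi 4-D array (x, y, z, volume).
#' @param gradient_table A `gradient_table` with >= 6 nonzero-b directions.
#' @param mask Logical 3-D array of voxels to fit.
#' @param signal_floor Clamp for nonpositive attenuations.
#' @return List with `tensors` (n_masked x 6: Dxx, Dyy, Dzz, Dxy, Dxz, Dyz),
#'   `s0` (vector), `md`, `fa` (vectors), `attenuations` (n_masked x nd),
#'   `mask`, `n_clamped`.
#' @export
fit_dti_loglinear <- function(dwi, gradient_table, mask,
                              signal_floor = 1e-4) {
  gt <- validate_gradient_table(gradient_table)
  if (!identical(dim(dwi)[1:3], dim(mask))) {
    stop("dimension error: DWI grid and mask disagree", call. = FALSE)
  }
  if (dim(dwi)[4] != length(gt$bvals)) {
    stop("dimension error: DWI volume count and gradient table disagree",
         call. = FALSE)
  }
  nz <- gt$bvals > 0
  if (sum(nz) < 6L) {
    stop("at least 6 nonzero-b directions are required", call. = FALSE)
  }
  mask <- as_mask(mask)
  vox <- which(mask)
  nvol <- dim(dwi)[4]
  S <- matrix(dwi, ncol = nvol)[vox, , drop = FALSE]   # n_masked x nvol
  s0 <- exp(rowMeans(log(pmax(S[, !nz, drop = FALSE], .Machine$double.xmin))))
  if (any(s0 <= 0) || any(!is.finite(s0))) {
    stop("nonpositive b=0 signal inside mask", call. = FALSE)
  }
  A <- S / s0
  n_clamped <- sum(A <= 0)
  A[A <= signal_floor] <- signal_floor
  X <- tensor_design(gt)[nz, , drop = FALSE]
  Y <- -log(A[, nz, drop = FALSE])            # n x nd
  XtXi <- solve(crossprod(X))
  tensors <- Y %*% X %*% XtXi                 # n x 6
  colnames(tensors) <- c("Dxx", "Dyy", "Dzz", "Dxy", "Dxz", "Dyz")
  md <- rowSums(tensors[, 1:3, drop = FALSE]) / 3
  list(tensors = tensors, s0 = s0, md = md,
       fa = fa_from_tensor6(tensors), attenuations = A, mask = mask,
       n_clamped = n_clamped)
}

#' Initial tissue-fraction map from mean diffusivity
#'
#' Linear interpolation between the free-water diffusivity and a reference
#' tissue diffusivity: `f_t = clip((d_w - MD) / (d_w - md_tissue_ref), eps,
#' 1 - eps)`. Monotone decreasing in MD: high observed diffusivity implies a
#' large free-water fraction.
#'
#' @param md Mean-diffusivity values (vector or array), mm^2/s.
#' @param d_w Free-water diffusivity, mm^2/s.
#' @param md_tissue_ref Reference tissue mean diffusivity, mm^2/s.
#' @param eps Clip margin.
#' @return Initial `f_t` values, same shape as `md`.
#' @export
init_freewater <- function(md, d_w = 3.0e-3, md_tissue_ref = 0.7e-3,
                           eps = 0.01) {
  if (!(d_w > md_tissue_ref && md_tissue_ref > 0)) {
    stop("require d_w > md_tissue_ref > 0", call. = FALSE)
  }
  pmin(pmax((d_w - md) / (d_w - md_tissue_ref), eps), 1 - eps)
}

## Scale-matching initial tissue fraction, consistent with the tissue-MD
## prior: rescale each log-linear tensor to md_tissue_ref, predict the mean
## tissue attenuation, and solve the mixture equation
##   mean(A_obs) = f * mean(A_tissue) + (1 - f) * exp(-b d_w)
## for f. On single-shell data the intercept of a log-linear fit is exactly
## collinear with the tensor trace, so this prior-based scale matching is the
## only initialization that sees the free-water compartment directly.
init_freewater_scale <- function(dti, gt, cfg) {
  nz <- gt$bvals > 0
  sc <- cfg$md_tissue_ref / pmax(dti$md, 1e-5)
  q <- (dti$tensors * sc) %*% t(tensor_design(gt)[nz, , drop = FALSE])
  At <- rowMeans(exp(-q))
  Aobs <- rowMeans(dti$attenuations[, nz, drop = FALSE])
  ciso <- mean(exp(-gt$bvals[nz] * cfg$d_w))
  pmin(pmax((Aobs - ciso) / pmax(At - ciso, 1e-6), cfg$eps), 1 - cfg$eps)
}

## Vectorized lower-triangular Cholesky of n x 6 tensors, with PSD repair.
chol6 <- function(t6, floor = 1e-12) {
  dxx <- pmax(t6[, 1], floor)
  l11 <- sqrt(dxx)
  l21 <- t6[, 4] / l11
  l31 <- t6[, 5] / l11
  l22 <- sqrt(pmax(t6[, 2] - l21^2, floor))
  l32 <- (t6[, 6] - l21 * l31) / l22
  l33 <- sqrt(pmax(t6[, 3] - l31^2 - l32^2, floor))
  cbind(l11, l21, l31, l22, l32, l33)
}

## L (n x 6: l11,l21,l31,l22,l32,l33) -> tensor 6-vector (n x 6)
ll_to_tensor6 <- function(L) {
  cbind(Dxx = L[, 1]^2,
        Dyy = L[, 2]^2 + L[, 4]^2,
        Dzz = L[, 3]^2 + L[, 5]^2 + L[, 6]^2,
        Dxy = L[, 1] * L[, 2],
        Dxz = L[, 1] * L[, 3],
        Dyz = L[, 2] * L[, 3] + L[, 4] * L[, 5])
}

## FA from tensor invariants (valid for PSD tensors): n x 6 -> n
fa_from_tensor6 <- function(t6) {
  tr <- t6[, 1] + t6[, 2] + t6[, 3]
  tr2 <- t6[, 1]^2 + t6[, 2]^2 + t6[, 3]^2 +
    2 * (t6[, 4]^2 + t6[, 5]^2 + t6[, 6]^2)   # tr(D^2)
  num <- pmax(tr2 - tr^2 / 3, 0)
  fa <- sqrt(1.5 * num / pmax(tr2, .Machine$double.xmin))
  fa[tr2 <= 0] <- 0
  pmin(fa, 1)
}

#' Fractional anisotropy of a symmetric tensor
#'
#' `FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||` over the
#' eigenvalues; negative eigenvalues are clamped to zero before the formula
#' (a message reports how many), and the all-zero tensor has FA 0 by
#' definition.
#'
#' @param tensor Symmetric 3x3 matrix.
#' @return FA scalar in `[0, 1]`.
#' @export
compute_fa <- function(tensor) {
  if (!isTRUE(all.equal(tensor, t(tensor), tolerance = 1e-8))) {
    stop("tensor must be symmetric", call. = FALSE)
  }
  ev <- eigen(tensor, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < 0)) {
    message("compute_fa: clamped ", sum(ev < 0), " negative eigenvalue(s) to 0")
    ev <- pmax(ev, 0)
  }
  if (all(ev == 0)) return(0)
  m <- mean(ev)
  sqrt(1.5) * sqrt(sum((ev - m)^2)) / sqrt(sum(ev^2))
}

## Core batched Levenberg-Marquardt for the (penalized) bi-tensor model.
## A: n x nd attenuations; theta: n x 7 (f, l11,l21,l31,l22,l32,l33).
## Objective per voxel: sum_i (Ahat_i - A_i)^2
##   + lambda_reg * nd * (f - f_anchor)^2                 [spatial coupling]
##   + lambda_md * nd * ((tr(D)/3 - md_tissue_ref)/d_w)^2 [tissue-MD prior]
## Returns list(theta, n_iter, converged, cost).
lm_bitensor <- function(A, theta, gt, cfg, f_anchor = NULL) {
  n <- nrow(A)
  b <- gt$bvals
  g <- gt$bvecs
  nd <- length(b)
  ciso <- exp(-b * cfg$d_w)
  p <- 7L
  sf <- if (!is.null(f_anchor) && cfg$lambda_reg > 0)
    sqrt(cfg$lambda_reg * nd) else 0
  sm <- if ((cfg$lambda_md %||% 0) > 0)
    sqrt(cfg$lambda_md * nd) / (3 * cfg$d_w) else 0

  predict_all <- function(th) {
    u1 <- th[, 2, drop = FALSE] %*% g[1, , drop = FALSE] +
          th[, 3, drop = FALSE] %*% g[2, , drop = FALSE] +
          th[, 4, drop = FALSE] %*% g[3, , drop = FALSE]
    u2 <- th[, 5, drop = FALSE] %*% g[2, , drop = FALSE] +
          th[, 6, drop = FALSE] %*% g[3, , drop = FALSE]
    u3 <- th[, 7, drop = FALSE] %*% g[3, , drop = FALSE]
    q <- sweep(u1^2 + u2^2 + u3^2, 2, b, "*")
    Et <- exp(-q)
    list(pred = th[, 1] * Et + outer(1 - th[, 1], ciso),
         Et = Et, u1 = u1, u2 = u2, u3 = u3)
  }
  penalty_cost <- function(th, rows) {
    out <- 0
    if (sf > 0) out <- out + (sf * (th[, 1] - f_anchor[rows]))^2
    if (sm > 0) {
      tr <- th[, 2]^2 + th[, 3]^2 + th[, 4]^2 + th[, 5]^2 + th[, 6]^2 +
        th[, 7]^2
      out <- out + (sm * (tr - 3 * cfg$md_tissue_ref))^2
    }
    out
  }
  total_cost <- function(th, rows) {
    rowSums((predict_all(th)$pred - A[rows, , drop = FALSE])^2) +
      penalty_cost(th, rows)
  }

  lam <- rep(1e-3, n)
  n_iter <- integer(n)
  converged <- logical(n)
  active <- seq_len(n)
  cost <- total_cost(theta, seq_len(n))

  for (it in seq_len(cfg$max_iter)) {
    if (length(active) == 0L) break
    th <- theta[active, , drop = FALSE]
    pr <- predict_all(th)
    R <- pr$pred - A[active, , drop = FALSE]
    fEt <- -th[, 1] * pr$Et
    ## Jacobian blocks of the data term (na x nd each)
    J <- vector("list", p)
    J[[1]] <- pr$Et - matrix(ciso, nrow(th), nd, byrow = TRUE)
    J[[2]] <- fEt * sweep(pr$u1, 2, 2 * b * g[1, ], "*")
    J[[3]] <- fEt * sweep(pr$u1, 2, 2 * b * g[2, ], "*")
    J[[4]] <- fEt * sweep(pr$u1, 2, 2 * b * g[3, ], "*")
    J[[5]] <- fEt * sweep(pr$u2, 2, 2 * b * g[2, ], "*")
    J[[6]] <- fEt * sweep(pr$u2, 2, 2 * b * g[3, ], "*")
    J[[7]] <- fEt * sweep(pr$u3, 2, 2 * b * g[3, ], "*")

    na <- length(active)
    H <- array(0, c(na, p, p))
    grad <- matrix(0, na, p)
    for (a in seq_len(p)) {
      Ja <- J[[a]]
      grad[, a] <- rowSums(Ja * R)
      for (bb in a:p) {
        hv <- rowSums(Ja * J[[bb]])
        H[, a, bb] <- hv
        H[, bb, a] <- hv
      }
    }
    if (sf > 0) {
      rf <- sf * (th[, 1] - f_anchor[active])
      grad[, 1] <- grad[, 1] + sf * rf
      H[, 1, 1] <- H[, 1, 1] + sf^2
    }
    if (sm > 0) {
      tr <- th[, 2]^2 + th[, 3]^2 + th[, 4]^2 + th[, 5]^2 + th[, 6]^2 +
        th[, 7]^2
      rm_ <- sm * (tr - 3 * cfg$md_tissue_ref)
      for (a in 2:7) {
        da <- sm * 2 * th[, a]
        grad[, a] <- grad[, a] + da * rm_
        for (bb in a:7) {
          H[, a, bb] <- H[, a, bb] + da * (sm * 2 * th[, bb])
          if (bb > a) H[, bb, a] <- H[, a, bb]
        }
      }
    }

    step <- matrix(0, na, p)
    la <- lam[active]
    for (v in seq_len(na)) {
      Hv <- H[v, , ]
      dg <- diag(Hv) * (1 + la[v])
      diag(Hv) <- dg + 1e-10 * (1 + max(dg))
      sv <- solve(Hv, grad[v, ])
      if (all(is.finite(sv))) step[v, ] <- sv
    }
    cand <- th - step
    cand[, 1] <- pmin(pmax(cand[, 1], cfg$eps), 1 - cfg$eps)
    new_cost <- total_cost(cand, active)
    old_cost <- cost[active]
    improved <- is.finite(new_cost) & new_cost <= old_cost
    idx_imp <- active[improved]
    theta[idx_imp, ] <- cand[improved, , drop = FALSE]
    cost[idx_imp] <- new_cost[improved]
    lam[idx_imp] <- pmax(lam[idx_imp] / 3, 1e-10)
    lam[active[!improved]] <- pmin(lam[active[!improved]] * 4, 1e10)
    n_iter[active] <- it
    step_inf <- abs(step[, 1])
    for (a in 2:p) step_inf <- pmax(step_inf, abs(step[, a]))
    step_small <- step_inf < cfg$tol
    flat <- improved & (old_cost - new_cost) <= cfg$ftol * (new_cost + 1e-300)
    done <- improved & (step_small | flat)
    stuck <- !improved & lam[active] >= 1e10
    converged[active[done]] <- TRUE
    active <- active[!(done | stuck)]
  }
  list(theta = theta, n_iter = n_iter, converged = converged, cost = cost)
}

## Mean of the (up to 6) face neighbours inside `mask` for a scalar field.
neighbor_mean6 <- function(field, mask) {
  acc <- array(0, dim(mask))
  cnt <- array(0, dim(mask))
  fm <- field
  fm[!mask] <- 0
  for (axis in 1:3) for (dir in c(1L, -1L)) {
    acc <- acc + shift1_num(fm, axis, dir)
    cnt <- cnt + shift1(mask, axis, dir)
  }
  out <- field
  has <- mask & cnt > 0
  out[has] <- acc[has] / cnt[has]
  out
}

shift1_num <- function(m, axis, dir) {
  d <- dim(m)
  out <- array(0, d)
  n <- d[axis]
  if (n < 2L) return(out)
  if (axis == 1L) {
    if (dir > 0) out[2:n, , ] <- m[1:(n - 1L), , ] else out[1:(n - 1L), , ] <- m[2:n, , ]
  } else if (axis == 2L) {
    if (dir > 0) out[, 2:n, ] <- m[, 1:(n - 1L), ] else out[, 1:(n - 1L), ] <- m[, 2:n, ]
  } else {
    if (dir > 0) out[, , 2:n] <- m[, , 1:(n - 1L)] else out[, , 1:(n - 1L)] <- m[, , 2:n]
  }
  out
}

#' Fit the two-compartment free-water model
#'
#' Voxelwise constrained nonlinear least squares on signal attenuations:
#' minimizes `sum_i (Ahat_i - A_i)^2` over the tissue fraction `f_t`
#' (box-constrained to `[eps, 1 - eps]`) and the tissue tensor `D_t` (kept
#' positive semidefinite through a triangular-factor parameterization), with a
#' batched Levenberg-Marquardt solver. Initialization is a log-linear DTI fit
#' plus the mean-diffusivity interpolation of [init_freewater()], unless an
#' explicit `init` is supplied. With `lambda_reg > 0`, each outer iteration
#' adds a quadratic penalty pulling `f_t` toward the 6-neighbour mean of the
#' previous iterate (an iterated-Tikhonov smoothness term standing in for the
#' original gradient-flow regularization); `lambda_md > 0` adds a soft prior
#' anchoring the tissue mean diffusivity to `md_tissue_ref`, which breaks the
#' single-shell degeneracy between the free-water fraction and the tensor
#' trace. Voxels that fail to converge keep their best iterate and are
#' flagged, never aborting the volume.
#'
#' @param dwi 4-D array of signals (x, y, z, volume).
#' @param gradient_table A `gradient_table`.
#' @param mask Logical 3-D array of voxels to fit.
#' @param config A [fw_fit_config()].
#' @param init Optional list with `f_t` (vector over masked voxels, or 3-D
#'   array) and `tensors` (n_masked x 6) to start from (e.g., ground truth in
#'   simulations).
#' @return Object of class `freewater_fit`: arrays `fw_map`, `fat_map`,
#'   `md_t_map`, `residual_map` (RMS), `n_iter_map`, `converged_map`, logical
#'   `mask`, matrix `tensors`, vector `s0`, the `config`, and `n_clamped`.
#' @export
fit_bitensor <- function(dwi, gradient_table, mask, config = fw_fit_config(),
                         init = NULL) {
  stopifnot(inherits(config, "fw_fit_config"))
  gt <- validate_gradient_table(gradient_table)
  dti <- fit_dti_loglinear(dwi, gt, mask, signal_floor = config$signal_floor)
  A <- dti$attenuations
  vox <- which(dti$mask)
  n <- length(vox)

  if (is.null(init)) {
    f0 <- init_freewater_scale(dti, gt, config)
    ## tensor init: the log-linear tensor (free-water contamination is mild at
    ## high b; PSD is restored by the chol6 repair)
    t0 <- dti$tensors
  } else {
    f0 <- if (is.array(init$f_t)) init$f_t[dti$mask] else init$f_t
    f0 <- pmin(pmax(f0, config$eps), 1 - config$eps)
    t0 <- init$tensors
  }
  theta <- cbind(f0, chol6(t0))

  n_outer <- if (config$lambda_reg > 0) max(config$n_outer, 1L) else 1L
  res <- NULL
  total_iter <- integer(n)
  anchor <- NULL
  for (outer in seq_len(n_outer)) {
    if (config$lambda_reg > 0) {
      ## anchor: 6-neighbour mean of the current f field (init on first pass)
      f_field <- array(NA_real_, dim(dti$mask))
      f_field[dti$mask] <- theta[, 1]
      anchor <- neighbor_mean6(f_field, dti$mask)[dti$mask]
    }
    res <- lm_bitensor(A, theta, gt, config, f_anchor = anchor)
    theta <- res$theta
    total_iter <- total_iter + res$n_iter
  }
  res$n_iter <- total_iter

  t6 <- ll_to_tensor6(theta[, 2:7, drop = FALSE])
  pred <- forward_attenuation(theta[, 1], t6, gt, config$d_w)
  rms <- sqrt(rowMeans((pred - A)^2))

  gs <- dim(dti$mask)
  blank <- array(NA_real_, gs)
  fw_map <- fat_map <- md_map <- res_map <- blank
  it_map <- array(NA_integer_, gs)
  cv_map <- array(NA, gs)
  fw_map[vox] <- 1 - theta[, 1]
  fat_map[vox] <- fa_from_tensor6(t6)
  md_map[vox] <- rowSums(t6[, 1:3, drop = FALSE]) / 3
  res_map[vox] <- rms
  it_map[vox] <- res$n_iter
  cv_map[vox] <- res$converged
  n_fail <- sum(!res$converged)
  if (n_fail > 0) {
    message("fit_bitensor: ", n_fail, "/", n,
            " voxel(s) did not reach tol; best iterates retained")
  }
  structure(list(fw_map = fw_map, fat_map = fat_map, md_t_map = md_map,
                 residual_map = res_map, n_iter_map = it_map,
                 converged_map = cv_map, mask = dti$mask, tensors = t6,
                 s0 = dti$s0, config = config, n_clamped = dti$n_clamped),
            class = "freewater_fit")
}

#' @export
print.freewater_fit <- function(x, ...) {
  v <- x$mask
  cat(sprintf("Free-water fit: %d voxels, fw %.3f [%.3f, %.3f], FA-T %.3f, RMS %.2e\n",
              sum(v), stats::median(x$fw_map[v]), min(x$fw_map[v]),
              max(x$fw_map[v]), stats::median(x$fat_map[v]),
              stats::median(x$residual_map[v])))
  invisible(x)
}
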
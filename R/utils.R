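#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

## Derive a stream-specific child seed from a base seed (kept < 2^31).
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 1103515245 + stream * 12345) %% 2147483647
}

stopifnot_mask <- function(m, name = deparse(substitute(m))) {
  if (!is.array(m) || length(dim(m)) != 3L) {
    stop(sprintf("'%s' must be a 3-D array", name), call. = FALSE)
  }
  v <- unique(as.vector(m))
  if (!all(v %in% c(0, 1, TRUE, FALSE))) {
    stop(sprintf("non-binary mask '%s'", name), call. = FALSE)
  }
  invisible(TRUE)
}

as_mask <- function(m) {
  storage.mode(m) <- "logical"
  m
}

same_grid <- function(a, b) identical(dim(a), dim(b))

## Shift a 3-D logical array by one voxel along an axis, zero-padded.
shift1 <- function(m, axis, dir) {
  d <- dim(m)
  out <- array(FALSE, d)
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
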
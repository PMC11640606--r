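# Internal helpers shared across the pipeline.

#' @keywords internal
`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate an expression with a locally seeded RNG, restoring the caller's
# RNG state afterwards so generators never perturb global randomness.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}

# Shift a 3D array (T x Y x X) by `k` positions along `axis`, replicating the
# edge slice. Used by the separable Gaussian smoother and motion artifacts.
shift_array <- function(x, k, axis) {
  if (k == 0L) return(x)
  d <- dim(x)
  n <- d[axis]
  idx <- seq_len(n) - k
  idx[idx < 1L] <- 1L
  idx[idx > n] <- n
  switch(axis,
         x[idx, , , drop = FALSE],
         x[, idx, , drop = FALSE],
         x[, , idx, drop = FALSE])
}

# Separable Gaussian smoothing of a T x Y x X array via shift-and-add with
# edge replication; sigma is in samples along the given axis, 0 disables.
gaussian_smooth_axis <- function(x, sigma, axis) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  w <- stats::dnorm(-r:r, sd = sigma)
  w <- w / sum(w)
  out <- array(0, dim = dim(x))
  for (i in seq_along(w)) {
    out <- out + w[i] * shift_array(x, (-r:r)[i], axis)
  }
  out
}

# Vectorized median of three arrays.
median3 <- function(a, b, c) pmax(pmin(a, b), pmin(pmax(a, b), c))

# Column-major pixel index helpers for Y x X frames.
pixel_index <- function(y, x, ny) (x - 1L) * ny + y
pixel_yx <- function(idx, ny) {
  cbind(y = ((idx - 1L) %% ny) + 1L, x = ((idx - 1L) %/% ny) + 1L)
}
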
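#' Fit per-pixel basal fluorescence F0 by least-squares polynomial
#'
#' For every pixel, a polynomial of the given degree is fitted to the
#' intensity time course in a least-squares sense on a centered and scaled
#' time axis (for conditioning). With `robust_iterations > 0` the fit is
#' iteratively re-estimated excluding frames whose *positive* residual
#' exceeds `robust_k` noise standard deviations, so that Ca2+ transients do
#' not inflate the baseline. The per-pixel noise scale is estimated from the
#' negative residuals only (noise is symmetric about the baseline while
#' transients are strictly positive, so the lower residual half is
#' event-free). The exclusion refit solves
#' the masked least-squares problem by an imputation fixed point (masked
#' frames are replaced by the current fit and the full design refitted until
#' the coefficients converge), which keeps the whole stack vectorized.
#'
#' With `robust_iterations = 0` the result is the exact closed-form
#' normal-equations solution, and a trace that is itself a polynomial of
#' degree `<= degree` is interpolated exactly.
#'
#' @param movie a [ca_movie()].
#' @param degree polynomial degree (non-negative; `degree + 1 <= T`).
#' @param robust_iterations number of event-exclusion refits (default 2).
#' @param robust_k positive-residual exclusion threshold in residual sds.
#' @return An object of class `f0_model`: coefficients per pixel (on the
#'   scaled time axis), the time scaling, and a logical `masked` map of
#'   pixels whose evaluated F0 is non-positive at any frame (all-zero or
#'   otherwise degenerate traces).
#' @export
fit_f0 <- function(movie, degree = 3L, robust_iterations = 2L,
                   robust_k = 2) {
  stopifnot(inherits(movie, "ca_movie"))
  d <- dim(movie$data)
  T <- d[1]
  if (degree < 0) stop("`degree` must be >= 0", call. = FALSE)
  if (degree + 1 > T) {
    stop("`degree` + 1 must not exceed the number of frames", call. = FALSE)
  }
  tt <- frame_times(movie)
  ctr <- mean(tt)
  scl <- if (T > 1) stats::sd(tt) else 1
  s <- (tt - ctr) / scl
  X <- outer(s, 0:degree, `^`)
  XtX <- crossprod(X)
  A <- solve(XtX, t(X))                      # (p+1) x T projector

  P <- d[2] * d[3]
  beta <- matrix(0, degree + 1, P)
  masked_v <- logical(P)
  # fit in pixel blocks (x-slabs) to bound transient memory on large stacks
  x_blocks <- split(seq_len(d[3]), ceiling(seq_len(d[3]) / ceiling(d[3] / 16)))
  for (xs in x_blocks) {
    cols <- rep((xs - 1L) * d[2], each = d[2]) + seq_len(d[2])
    Y <- matrix(movie$data[, , xs, drop = FALSE], nrow = T)
    b <- A %*% Y
    if (robust_iterations > 0) {
      for (it in seq_len(robust_iterations)) {
        fitted <- X %*% b
        resid <- Y - fitted
        # noise scale from negative residuals only: transients are strictly
        # positive, so the lower residual half is event-free
        neg <- resid < 0
        nneg <- pmax(colSums(neg), 1)
        sig <- sqrt(colSums(resid^2 * neg) / nneg)
        mask <- resid > rep(robust_k * sig, each = T)
        mask <- mask & rep(sig > 0, each = T)
        if (!any(mask)) break
        Yimp <- Y
        Yimp[mask] <- fitted[mask]
        prev <- b
        for (inner in 1:25) {
          b <- A %*% Yimp
          fit_in <- X %*% b
          Yimp[mask] <- fit_in[mask]
          if (max(abs(b - prev)) < 1e-10 * (1 + max(abs(b)))) break
          prev <- b
        }
      }
    }
    beta[, cols] <- b
    f0b <- X %*% b
    masked_v[cols] <- apply(f0b <= 0, 2, any) | colSums(abs(Y)) == 0
  }
  masked <- matrix(masked_v, d[2], d[3])
  structure(
    list(degree = as.integer(degree), coefficients = beta,
         time_center = ctr, time_scale = scl,
         robust_iterations = as.integer(robust_iterations),
         robust_k = robust_k, masked = masked,
         dims = d, frame_interval_s = movie$frame_interval_s),
    class = "f0_model"
  )
}

#' @export
print.f0_model <- function(x, ...) {
  cat(sprintf(
    "<f0_model> degree %d | %d robust iteration(s) | %d/%d pixels masked\n",
    x$degree, x$robust_iterations, sum(x$masked), length(x$masked)))
  invisible(x)
}

#' Evaluate a fitted baseline over the recording
#'
#' @param object an `f0_model`.
#' @param ... unused.
#' @return `T x Y x X` array of fitted F0.
#' @export
predict.f0_model <- function(object, ...) {
  T <- object$dims[1]
  tt <- (seq_len(T) - 1) * object$frame_interval_s
  s <- (tt - object$time_center) / object$time_scale
  X <- outer(s, 0:object$degree, `^`)
  array(X %*% object$coefficients, dim = object$dims)
}

#' Normalize a movie to dF/F0
#'
#' Computes `(F - F0) / F0` per pixel and frame against the fitted baseline.
#' Pixels flagged in the baseline model (non-positive F0 at any frame, e.g.
#' all-zero traces) are masked: their dF/F0 is `NA` at every frame, and the
#' number of masked pixels is reported with a message.
#'
#' @param movie the [ca_movie()] the baseline was fitted on (same geometry).
#' @param baseline an [fit_f0()] model.
#' @return object of class `dff_stack`: list with `data` (T x Y x X dF/F0),
#'   the calibration, and the logical `mask` of dropped pixels.
#' @export
compute_dff <- function(movie, baseline) {
  stopifnot(inherits(movie, "ca_movie"), inherits(baseline, "f0_model"))
  if (!identical(dim(movie$data), baseline$dims)) {
    stop("baseline was fitted on a different geometry", call. = FALSE)
  }
  d <- baseline$dims
  T <- d[1]
  tt <- (seq_len(T) - 1) * baseline$frame_interval_s
  s <- (tt - baseline$time_center) / baseline$time_scale
  X <- outer(s, 0:baseline$degree, `^`)
  dff <- array(NA_real_, dim = d)
  # evaluate F0 and normalize in x-slabs so the full F0 stack never exists
  x_blocks <- split(seq_len(d[3]), ceiling(seq_len(d[3]) / ceiling(d[3] / 16)))
  for (xs in x_blocks) {
    cols <- rep((xs - 1L) * d[2], each = d[2]) + seq_len(d[2])
    f0b <- X %*% baseline$coefficients[, cols, drop = FALSE]
    dff[, , xs] <- (matrix(movie$data[, , xs, drop = FALSE], nrow = T) - f0b) / f0b
  }
  if (any(baseline$masked)) {
    bad <- which(baseline$masked)
    m <- matrix(dff, nrow = T)
    m[, bad] <- NA_real_
    dff <- array(m, dim = d)
    message(sum(baseline$masked),
            " pixel(s) masked (non-positive fitted F0)")
  }
  structure(
    list(data = dff, pixel_size_um = movie$pixel_size_um,
         frame_interval_s = movie$frame_interval_s,
         mask = baseline$masked),
    class = "dff_stack"
  )
}

#' @export
print.dff_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dff_stack> %d frames of %d x %d px | %d masked pixel(s)\n",
              d[1], d[2], d[3], sum(x$mask)))
  invisible(x)
}

#' Temporal range projection of a dF/F0 stack
#'
#' Per-pixel `max - min` of dF/F0 over time: the map on which local maxima
#' are picked as seed points for region growing. Masked pixels are `NA`.
#'
#' @param dff a [compute_dff()] stack.
#' @return object of class `range_map`: list with `data` (Y x X matrix,
#'   values >= 0 or NA) and the pixel size.
#' @export
range_projection <- function(dff) {
  stopifnot(inherits(dff, "dff_stack"))
  d <- dim(dff$data)
  if (d[1] < 2) stop("need at least 2 frames", call. = FALSE)
  hi <- dff$data[1, , ]; lo <- hi
  for (t in 2:d[1]) {
    fr <- dff$data[t, , ]
    hi <- pmax(hi, fr)
    lo <- pmin(lo, fr)
  }
  structure(list(data = matrix(hi - lo, d[2], d[3]),
                 pixel_size_um = dff$pixel_size_um),
            class = "range_map")
}

#' @export
print.range_map <- function(x, ...) {
  cat(sprintf("<range_map> %d x %d px | median %.3g | max %.3g\n",
              nrow(x$data), ncol(x$data),
              stats::median(x$data, na.rm = TRUE),
              max(x$data, na.rm = TRUE)))
  invisible(x)
}
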
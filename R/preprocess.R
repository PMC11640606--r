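#' Preprocessing configuration
#'
#' @param median_window_frames odd window (frames) of the temporal median
#'   filter; 3 is the smallest window that removes a single displaced frame
#'   while retaining sharp transient edges.
#' @param denoiser `"none"` or `"variance_stabilized_smoothing"` (Anscombe
#'   variance-stabilizing transform followed by separable Gaussian smoothing,
#'   then the algebraic inverse transform).
#' @param sigma_t_frames temporal Gaussian sd in frames (0 disables).
#' @param sigma_s_px spatial Gaussian sd in pixels (0 disables; the default
#'   is temporal-only smoothing, which reduces noise without bleeding event
#'   signal into neighboring pixels).
#' @param order `"median_first"` (default) or `"denoise_first"`.
#' @return list of class `preprocess_config`.
#' @export
preprocess_config <- function(median_window_frames = 3L,
                              denoiser = c("variance_stabilized_smoothing",
                                           "none"),
                              sigma_t_frames = 0.75, sigma_s_px = 0,
                              order = c("median_first", "denoise_first")) {
  denoiser <- match.arg(denoiser)
  order <- match.arg(order)
  if (median_window_frames < 1 || median_window_frames %% 2 == 0) {
    stop("`median_window_frames` must be a positive odd integer",
         call. = FALSE)
  }
  if (sigma_t_frames < 0 || sigma_s_px < 0) {
    stop("smoothing sigmas must be >= 0", call. = FALSE)
  }
  structure(list(median_window_frames = as.integer(median_window_frames),
                 denoiser = denoiser, sigma_t_frames = sigma_t_frames,
                 sigma_s_px = sigma_s_px, order = order),
            class = "preprocess_config")
}

#' Temporal median filter
#'
#' Replaces every pixel's time course by its running median, which removes
#' single displaced frames (small motion artifacts) while retaining sharp
#' transient edges. Edge frames are handled by shrinking the window
#' (`stats::runmed` end rule `"median"`), so array dimensions and
#' calibration are unchanged.
#'
#' @param movie a [ca_movie()].
#' @param window odd window length in frames, `<= T`.
#' @return a filtered [ca_movie()].
#' @export
temporal_median_filter <- function(movie, window = 3L) {
  stopifnot(inherits(movie, "ca_movie"))
  T <- dim(movie$data)[1]
  if (window %% 2 == 0) stop("`window` must be odd", call. = FALSE)
  if (window > T) stop("`window` exceeds the number of frames", call. = FALSE)
  if (window == 1L) return(movie)
  data <- movie$data
  if (window == 3L) {
    # vectorized median-of-three, chunked along x to bound transient memory
    out <- data
    if (T >= 3L) {
      nx <- dim(data)[3]
      for (xs in split(seq_len(nx), ceiling(seq_len(nx) / ceiling(nx / 8)))) {
        a <- data[1:(T - 2), , xs, drop = FALSE]
        b <- data[2:(T - 1), , xs, drop = FALSE]
        c <- data[3:T, , xs, drop = FALSE]
        out[2:(T - 1), , xs] <- median3(a, b, c)
      }
    }
  } else {
    d <- dim(data)
    m <- matrix(data, nrow = T)
    out <- vapply(seq_len(ncol(m)), function(j) {
      as.numeric(stats::runmed(m[, j], window, endrule = "median"))
    }, numeric(T))
    out <- array(out, dim = d)
  }
  ca_movie(out, movie$pixel_size_um, movie$frame_interval_s)
}

#' Denoise a movie
#'
#' `"none"` is the identity. `"variance_stabilized_smoothing"` applies the
#' Anscombe transform `2 * sqrt(x + 3/8)` (approximately unit variance under
#' Poisson-like noise), separable Gaussian smoothing along time and
#' optionally space, and the algebraic inverse. Smoothing strictly reduces
#' per-pixel temporal variance on noise-only movies and preserves the mean
#' intensity to well within 1% at typical photon counts.
#'
#' @param movie a [ca_movie()].
#' @param config a [preprocess_config()].
#' @return a denoised [ca_movie()].
#' @export
denoise <- function(movie, config = preprocess_config()) {
  stopifnot(inherits(movie, "ca_movie"))
  if (!inherits(config, "preprocess_config")) {
    stop("`config` must be a preprocess_config", call. = FALSE)
  }
  if (config$denoiser == "none") return(movie)
  u <- 2 * sqrt(movie$data + 3 / 8)
  u <- gaussian_smooth_axis(u, config$sigma_t_frames, 1L)
  u <- gaussian_smooth_axis(u, config$sigma_s_px, 2L)
  u <- gaussian_smooth_axis(u, config$sigma_s_px, 3L)
  out <- pmax((u / 2)^2 - 3 / 8, 0)
  ca_movie(out, movie$pixel_size_um, movie$frame_interval_s)
}

#' Run the full preprocessing stage
#'
#' Applies the temporal median filter and the denoiser in the configured
#' order (median filter first by default, so single displaced frames are
#' removed before any smoothing can spread them).
#'
#' @param movie a [ca_movie()].
#' @param config a [preprocess_config()].
#' @return a preprocessed [ca_movie()].
#' @export
preprocess_movie <- function(movie, config = preprocess_config()) {
  if (config$order == "median_first") {
    movie <- temporal_median_filter(movie, config$median_window_frames)
    denoise(movie, config)
  } else {
    movie <- denoise(movie, config)
    temporal_median_filter(movie, config$median_window_frames)
  }
}
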
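#' Calcium imaging movie container
#'
#' A `ca_movie` is a time-lapse fluorescence stack together with its physical
#' calibration: the pixel size in micrometers and the frame interval in
#' seconds. Data are stored as a `T x Y x X` array of non-negative
#' intensities (arbitrary units).
#'
#' @param data numeric `T x Y x X` array of finite, non-negative intensities
#'   with at least two frames.
#' @param pixel_size_um pixel edge length in micrometers (positive scalar).
#' @param frame_interval_s time between consecutive frames in seconds
#'   (positive scalar).
#'
#' @return An object of class `ca_movie`: a list with elements `data`,
#'   `pixel_size_um` and `frame_interval_s`.
#' @export
ca_movie <- function(data, pixel_size_um, frame_interval_s) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a T x Y x X array", call. = FALSE)
  }
  if (dim(data)[1] < 2L) stop("a movie needs at least 2 frames", call. = FALSE)
  if (anyNA(data) || any(!is.finite(data))) {
    stop("movie intensities must be finite", call. = FALSE)
  }
  if (any(data < 0)) stop("movie intensities must be >= 0", call. = FALSE)
  stopifnot_scalar_pos(pixel_size_um, "pixel_size_um")
  stopifnot_scalar_pos(frame_interval_s, "frame_interval_s")
  structure(
    list(data = data, pixel_size_um = pixel_size_um,
         frame_interval_s = frame_interval_s),
    class = "ca_movie"
  )
}

#' @export
print.ca_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<ca_movie> %d frames of %d x %d px | %.3g um/px | %.3g s/frame (%.3g s)\n",
    d[1], d[2], d[3], x$pixel_size_um, x$frame_interval_s,
    d[1] * x$frame_interval_s))
  invisible(x)
}

#' @export
dim.ca_movie <- function(x) dim(x$data)

#' Frame times of a movie
#'
#' @param movie a [ca_movie()].
#' @return numeric vector of frame onset times in seconds, starting at 0.
#' @export
frame_times <- function(movie) {
  (seq_len(dim(movie$data)[1]) - 1) * movie$frame_interval_s
}

#' Field-of-view area of a movie in square micrometers
#'
#' @param movie a [ca_movie()].
#' @return scalar area in um^2.
#' @export
fov_area_um2 <- function(movie) {
  d <- dim(movie$data)
  d[2] * d[3] * movie$pixel_size_um^2
}

#' Write / read a movie as multi-page TIFF with a JSON sidecar
#'
#' Movies are serialized as 16-bit multi-page TIFF (one page per frame)
#' plus a `<path>.json` sidecar holding the calibration, the intensity
#' scale used for 16-bit packing, and an optional configuration echo, so a
#' round trip preserves both the data (to 16-bit quantization) and the
#' physical units.
#'
#' @param movie a [ca_movie()].
#' @param path output TIFF path; the sidecar is written next to it.
#' @param config_echo optional list echoed verbatim into the sidecar.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path, config_echo = NULL) {
  scale <- max(movie$data, 1e-12)
  pages <- lapply(seq_len(dim(movie$data)[1]), function(t) {
    movie$data[t, , ] / scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  sidecar <- list(
    pixel_size_um = movie$pixel_size_um,
    frame_interval_s = movie$frame_interval_s,
    intensity_scale = scale,
    n_frames = dim(movie$data)[1]
  )
  if (!is.null(config_echo)) sidecar$config <- config_echo
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) {
    stop("missing calibration sidecar: ", meta_path, call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- dim(pages[[1]])
  data <- array(0, dim = c(length(pages), d[1], d[2]))
  for (t in seq_along(pages)) data[t, , ] <- pages[[t]] * meta$intensity_scale
  ca_movie(data, meta$pixel_size_um, meta$frame_interval_s)
}
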
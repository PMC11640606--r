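# Fixtures are built in code at test time; nothing is stored on disk.

# A constant-intensity movie.
flat_movie <- function(T = 20, ny = 8, nx = 8, value = 100,
                       pixel_size_um = 0.8, frame_interval_s = 0.5) {
  ca_movie(array(value, dim = c(T, ny, nx)), pixel_size_um, frame_interval_s)
}

# A dF/F0 stack built directly from a T x Y x X array (for tests that need
# exact control over traces, bypassing baseline fitting).
dff_from_array <- function(arr, pixel_size_um = 0.8, frame_interval_s = 0.5) {
  structure(
    list(data = arr, pixel_size_um = pixel_size_um,
         frame_interval_s = frame_interval_s,
         mask = matrix(FALSE, dim(arr)[2], dim(arr)[3])),
    class = "dff_stack"
  )
}

# A small movie_config for fast unit tests.
small_config <- function(...) {
  args <- utils::modifyList(
    list(height_px = 64L, width_px = 64L, duration_s = 90,
         n_events = 3L, event_area_um2_range = c(10, 40),
         motion_artifact_rate = 1, rng_seed = 42L),
    list(...))
  do.call(movie_config, args)
}

# Standardize a vector, and construct a companion with an exact Pearson
# correlation `rho` to it using `noise` orthogonalized against it.
trace_with_correlation <- function(target, noise, rho) {
  zt <- (target - mean(target)) / stats::sd(target)
  n0 <- noise - mean(noise)
  n0 <- n0 - zt * sum(n0 * zt) / sum(zt * zt)
  zn <- n0 / stats::sd(n0)
  rho * zt + sqrt(1 - rho^2) * zn
}
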
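#' Configuration for synthetic two-photon movies
#'
#' Builds the parameter set for [make_movie()]. Defaults emulate a 5-minute
#' in vivo two-photon acquisition of a 256 x 256 px field: 2 Hz frame rate,
#' 0.8 um/px (so the 5 um^2 minimum ROA area corresponds to ~8 pixels),
#' a slowly bleaching baseline, shot-like noise, and occasional single-frame
#' motion artifacts. Event amplitudes are expressed in dF/F0 units; the
#' default amplitude floor of 0.5 on a baseline of 100 a.u. with Gaussian
#' noise of sd 8 keeps the weakest event at a peak SNR of at least 5.
#'
#' @param height_px,width_px frame size in pixels.
#' @param pixel_size_um pixel edge length (um).
#' @param frame_interval_s seconds per frame (2 Hz default).
#' @param duration_s recording length in seconds.
#' @param baseline_level basal fluorescence F0 at t = 0 (a.u.).
#' @param bleach_fraction fractional intensity lost to photobleaching over
#'   the full recording, in `[0, 1)`; applied as a single smooth exponential.
#' @param noise_model `"gaussian"` (additive, `noise_sd`) or
#'   `"poisson_gaussian"` (Poisson shot noise with `gain` a.u. per photon
#'   plus Gaussian read noise `read_sd`).
#' @param noise_sd,gain,read_sd noise parameters (a.u.).
#' @param n_events number of Ca2+ transients to inject.
#' @param events_per_site number of transients sharing one footprint (a
#'   "site" plays the role of one active microdomain; > 1 exercises per-ROA
#'   frequency estimation).
#' @param event_area_um2_range min/max footprint area (um^2).
#' @param event_amplitude_dff_range min/max peak amplitude (dF/F0).
#' @param event_rise_s,event_decay_s time constants of the transient kernel.
#' @param motion_artifact_rate expected number of single displaced frames
#'   per recording (Poisson).
#' @param rng_seed integer seed; identical seed and config give bit-identical
#'   output.
#'
#' @return A list of class `movie_config`.
#' @seealso [make_movie()], [preset_movie_config()]
#' @export
movie_config <- function(height_px = 256L, width_px = 256L,
                         pixel_size_um = 0.8, frame_interval_s = 0.5,
                         duration_s = 300, baseline_level = 100,
                         bleach_fraction = 0.2,
                         noise_model = c("gaussian", "poisson_gaussian"),
                         noise_sd = 8, gain = 2, read_sd = 3,
                         n_events = 50L, events_per_site = 1L,
                         event_area_um2_range = c(10, 120),
                         event_amplitude_dff_range = c(0.5, 2),
                         event_rise_s = 0.8, event_decay_s = 3.2,
                         motion_artifact_rate = 2, rng_seed = 1L) {
  noise_model <- match.arg(noise_model)
  for (nm in c("pixel_size_um", "frame_interval_s", "duration_s",
               "baseline_level", "event_rise_s", "event_decay_s")) {
    stopifnot_scalar_pos(get(nm), nm)
  }
  if (height_px < 2 || width_px < 2) {
    stop("frame dimensions must be positive (>= 2 px)", call. = FALSE)
  }
  if (bleach_fraction < 0 || bleach_fraction >= 1) {
    stop("`bleach_fraction` must lie in [0, 1)", call. = FALSE)
  }
  if (duration_s / frame_interval_s < 10) {
    stop("recording must span at least 10 frames", call. = FALSE)
  }
  if (n_events < 0) stop("`n_events` must be >= 0", call. = FALSE)
  if (events_per_site < 1) stop("`events_per_site` must be >= 1", call. = FALSE)
  if (length(event_area_um2_range) != 2L || any(event_area_um2_range <= 0) ||
      diff(event_area_um2_range) < 0) {
    stop("`event_area_um2_range` must be positive (min, max)", call. = FALSE)
  }
  if (length(event_amplitude_dff_range) != 2L ||
      any(event_amplitude_dff_range <= 0) ||
      diff(event_amplitude_dff_range) < 0) {
    stop("`event_amplitude_dff_range` must be positive (min, max)",
         call. = FALSE)
  }
  if (motion_artifact_rate < 0 || !is.finite(motion_artifact_rate)) {
    stop("`motion_artifact_rate` must be finite and >= 0", call. = FALSE)
  }
  # largest footprint must fit within the frame with a safety margin
  max_r_px <- sqrt(max(event_area_um2_range) / pi) / pixel_size_um
  if (n_events > 0 && 2 * (max_r_px + 3) > min(height_px, width_px)) {
    stop("largest event footprint does not fit within the frame",
         call. = FALSE)
  }
  fields <- setdiff(names(formals(movie_config)), "...")
  structure(mget(fields), class = "movie_config")
}

#' Preset movie configurations for the two study-like conditions
#'
#' `"control"` emulates the quiescent condition: fewer, larger, longer-lasting
#' transients. `"cuprizone"` emulates the demyelinating condition's
#' statistical signature: more numerous, spatially smaller and briefer
#' transients. Only these statistics differ; acquisition geometry and noise
#' are shared.
#'
#' @param preset `"control"` or `"cuprizone"`.
#' @param rng_seed integer seed.
#' @param ... overrides forwarded to [movie_config()].
#' @return A `movie_config`.
#' @export
preset_movie_config <- function(preset = c("control", "cuprizone"),
                                rng_seed = 1L, ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    control = list(n_events = 40L, events_per_site = 2L,
                   event_area_um2_range = c(60, 110),
                   event_decay_s = 4, event_rise_s = 1,      # FWHM ~4.9 s
                   event_amplitude_dff_range = c(0.8, 1.8)),
    cuprizone = list(n_events = 80L, events_per_site = 2L,
                     event_area_um2_range = c(15, 55),
                     event_decay_s = 2.75, event_rise_s = 0.55, # FWHM ~3.2 s
                     event_amplitude_dff_range = c(0.8, 1.8))
  )
  args <- utils::modifyList(c(base, list(rng_seed = rng_seed)), list(...))
  do.call(movie_config, args)
}

#' Temporal kernel of a synthetic Ca2+ transient
#'
#' The default transient shape is the product of a rising and a decaying
#' exponential, `k(t) = (1 - exp(-t/rise)) * exp(-t/decay)` for `t >= 0`,
#' normalized to unit peak and scaled by `amplitude_dff`. Its full width at
#' half maximum is obtained by root finding on the continuous kernel, so the
#' generator knows each event's true FWHM analytically rather than from the
#' sampled trace. A symmetric Gaussian shape (`sigma_s`) is also available,
#' whose FWHM has the closed form `2 * sqrt(2 * log(2)) * sigma`.
#'
#' @param amplitude_dff peak amplitude in dF/F0 units (>= 0; 0 gives a flat
#'   zero trace).
#' @param rise_s,decay_s time constants (s) of the rise-decay kernel.
#' @param frame_interval_s sampling interval (s).
#' @param shape `"rise_decay"` or `"gaussian"`.
#' @param sigma_s Gaussian sd (s), used when `shape = "gaussian"`.
#'
#' @return list with `trace` (sampled kernel, unit time step
#'   `frame_interval_s`, starting at the event onset), `times` (s, relative
#'   to onset), `peak_offset_s` (continuous-time peak location relative to
#'   onset) and `fwhm_s` (half-maximum width of the continuous kernel).
#' @export
make_temporal_kernel <- function(amplitude_dff, rise_s = 0.5, decay_s = 2,
                                 frame_interval_s = 0.5,
                                 shape = c("rise_decay", "gaussian"),
                                 sigma_s = 1) {
  shape <- match.arg(shape)
  stopifnot_scalar_pos(frame_interval_s, "frame_interval_s")
  if (amplitude_dff < 0) stop("`amplitude_dff` must be >= 0", call. = FALSE)

  if (shape == "gaussian") {
    stopifnot_scalar_pos(sigma_s, "sigma_s")
    peak <- 4 * sigma_s                       # onset-relative peak position
    support <- 8 * sigma_s
    f <- function(t) exp(-(t - peak)^2 / (2 * sigma_s^2))
    fwhm <- 2 * sqrt(2 * log(2)) * sigma_s
  } else {
    stopifnot_scalar_pos(rise_s, "rise_s")
    stopifnot_scalar_pos(decay_s, "decay_s")
    peak <- rise_s * log1p(decay_s / rise_s)
    kraw <- function(t) ifelse(t <= 0, 0, (1 - exp(-t / rise_s)) * exp(-t / decay_s))
    kpeak <- kraw(peak)
    f <- function(t) kraw(t) / kpeak
    # support: decay until below 0.1% of peak
    support <- peak + decay_s * log(1000)
    # half-maximum crossings of the continuous kernel
    left <- stats::uniroot(function(t) f(t) - 0.5, c(1e-12, peak),
                           tol = 1e-10)$root
    upper <- peak + decay_s
    while (f(upper) > 0.5) upper <- upper + decay_s
    right <- stats::uniroot(function(t) f(t) - 0.5, c(peak, upper),
                            tol = 1e-10)$root
    fwhm <- right - left
  }
  if (frame_interval_s > support) {
    stop("frame interval exceeds the kernel's temporal support", call. = FALSE)
  }
  times <- seq(0, support, by = frame_interval_s)
  trace <- amplitude_dff * f(times)
  if (amplitude_dff == 0) trace <- rep(0, length(times))
  list(trace = trace, times = times, peak_offset_s = peak, fwhm_s = fwhm)
}

# Rasterize a filled ellipse footprint whose pixel count matches the target
# area; the radial scale is adjusted by bisection so the rasterized area is
# within one pixel of target_area_um2 (subject to pixel quantization).
rasterize_footprint <- function(center_yx, target_area_um2, pixel_size_um,
                                ecc, theta, ny, nx) {
  target_px <- target_area_um2 / pixel_size_um^2
  r0 <- sqrt(target_px / (pi * ecc))          # semi-axes r0*ecc (y), r0 (x)
  half <- ceiling(r0 * max(1, ecc)) + 2L
  ys <- (center_yx[1] - half):(center_yx[1] + half)
  xs <- (center_yx[2] - half):(center_yx[2] + half)
  ys <- ys[ys >= 1 & ys <= ny]
  xs <- xs[xs >= 1 & xs <= nx]
  dy <- outer(ys - center_yx[1], rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - center_yx[2])
  u <- cos(theta) * dy + sin(theta) * dx
  v <- -sin(theta) * dy + cos(theta) * dx
  q <- (u / ecc)^2 + v^2                      # <= s^2 * r0^2 inside
  count_at <- function(s) sum(q <= (s * r0)^2)
  lo <- 0.5; hi <- 1.6
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (count_at(mid) < target_px) lo <- mid else hi <- mid
  }
  inside <- q <= (hi * r0)^2
  yy <- outer(ys, rep(1L, length(xs)))[inside]
  xx <- outer(rep(1L, length(ys)), xs)[inside]
  pixel_index(yy, xx, ny)
}

#' Generate a synthetic movie with ground-truth events
#'
#' Composes `movie = F0(t) * (1 + sum of events) + noise`, where `F0(t)` is
#' the baseline under single-exponential photobleaching (deliberately not a
#' polynomial, so downstream polynomial baseline fitting is exercised under
#' model mismatch), events are filled-ellipse footprints modulated by the
#' rise-decay kernel of [make_temporal_kernel()], noise follows the
#' configured model, and an optional number of single frames is displaced by
#' 1-3 px to mimic motion artifacts. Negative intensities after noise are
#' clamped to zero and the clamp count is recorded in
#' `attr(movie$data, "n_clamped")`.
#'
#' Footprints are placed without spatial overlap; when `events_per_site > 1`
#' several transients share one footprint at well-separated times.
#'
#' @param config a [movie_config()].
#' @return list with `movie` (a [ca_movie()]) and `truth`, a data frame with
#'   one row per injected event (`event_id`, `site_id`, `center_y`,
#'   `center_x`, `area_um2`, `onset_s`, `peak_time_s`, `amplitude_dff`,
#'   `fwhm_s`) and the per-site pixel footprints in
#'   `attr(truth, "footprints")` (list indexed by `site_id`).
#' @export
make_movie <- function(config) {
  stopifnot(inherits(config, "movie_config"))
  cf <- config
  T <- as.integer(round(cf$duration_s / cf$frame_interval_s))
  ny <- as.integer(cf$height_px); nx <- as.integer(cf$width_px)
  tt <- (seq_len(T) - 1) * cf$frame_interval_s

  with_local_seed(cf$rng_seed, {
    # baseline with smooth monotone exponential bleaching
    bleach <- if (cf$bleach_fraction > 0) {
      lambda <- -log(1 - cf$bleach_fraction) / max(tt[T], cf$frame_interval_s)
      exp(-lambda * tt)
    } else {
      rep(1, T)
    }
    f0_t <- cf$baseline_level * bleach

    n_ev <- as.integer(cf$n_events)
    n_sites <- if (n_ev > 0) as.integer(ceiling(n_ev / cf$events_per_site)) else 0L

    # --- site footprints: non-overlapping filled ellipses -----------------
    footprints <- vector("list", n_sites)
    centers <- matrix(0L, n_sites, 2)
    areas_um2 <- numeric(n_sites)
    if (n_sites > 0) {
      max_r_px <- sqrt(max(cf$event_area_um2_range) / pi) / cf$pixel_size_um
      margin <- ceiling(max_r_px) + 3L
      placed_r <- numeric(0)
      for (s in seq_len(n_sites)) {
        target <- stats::runif(1, cf$event_area_um2_range[1],
                               cf$event_area_um2_range[2])
        r_px <- sqrt(target / pi) / cf$pixel_size_um
        ok <- FALSE
        for (try in 1:500) {
          cy <- sample.int(ny - 2L * margin, 1L) + margin
          cx <- sample.int(nx - 2L * margin, 1L) + margin
          if (s == 1L) { ok <- TRUE } else {
            dist <- sqrt((centers[seq_len(s - 1), 1] - cy)^2 +
                         (centers[seq_len(s - 1), 2] - cx)^2)
            ok <- all(dist > placed_r + r_px + 3)
          }
          if (ok) break
        }
        if (!ok) stop("could not place non-overlapping event footprints; ",
                      "reduce n_events or footprint areas", call. = FALSE)
        ecc <- stats::runif(1, 0.75, 1)       # mild eccentricity jitter
        theta <- stats::runif(1, 0, pi)
        fp <- rasterize_footprint(c(cy, cx), target, cf$pixel_size_um,
                                  ecc, theta, ny, nx)
        footprints[[s]] <- fp
        centers[s, ] <- c(cy, cx)
        areas_um2[s] <- length(fp) * cf$pixel_size_um^2
        placed_r <- c(placed_r, r_px)
      }
    }

    # --- event times and kernel ------------------------------------------
    kern <- make_temporal_kernel(1, cf$event_rise_s, cf$event_decay_s,
                                 cf$frame_interval_s)
    min_sep_s <- (kern$peak_offset_s + cf$event_decay_s * 4)
    truth <- NULL
    dff_true <- matrix(0, T, ny * nx)        # T x P ground-truth dF/F0
    if (n_ev > 0) {
      site_of <- rep(seq_len(n_sites), each = cf$events_per_site)[seq_len(n_ev)]
      onsets <- numeric(n_ev)
      lo <- 2 * cf$frame_interval_s
      hi <- cf$duration_s - kern$peak_offset_s - 2 * cf$frame_interval_s -
        min(3 * cf$event_decay_s, 0.2 * cf$duration_s)
      hi <- max(hi, lo + cf$frame_interval_s)
      for (s in seq_len(n_sites)) {
        idx <- which(site_of == s)
        for (try in 1:1000) {
          cand <- sort(stats::runif(length(idx), lo, hi))
          if (length(cand) < 2 || all(diff(cand) > min_sep_s)) break
        }
        onsets[idx] <- cand
      }
      amps <- stats::runif(n_ev, cf$event_amplitude_dff_range[1],
                           cf$event_amplitude_dff_range[2])
      for (e in seq_len(n_ev)) {
        fp <- footprints[[site_of[e]]]
        k0 <- which.min(abs(tt - onsets[e]))  # snap onset to frame grid
        t0 <- tt[k0]
        kidx <- k0 + seq_along(kern$trace) - 1L
        keep <- kidx <= T
        dff_true[kidx[keep], fp] <- dff_true[kidx[keep], fp] +
          amps[e] * kern$trace[keep]
        onsets[e] <- t0
      }
      truth <- data.frame(
        event_id = seq_len(n_ev),
        site_id = site_of,
        center_y = centers[site_of, 1],
        center_x = centers[site_of, 2],
        area_um2 = areas_um2[site_of],
        onset_s = onsets,
        peak_time_s = onsets + kern$peak_offset_s,
        amplitude_dff = amps,
        fwhm_s = kern$fwhm_s
      )
      truth <- truth[order(truth$event_id), , drop = FALSE]
    } else {
      truth <- data.frame(event_id = integer(), site_id = integer(),
                          center_y = integer(), center_x = integer(),
                          area_um2 = numeric(), onset_s = numeric(),
                          peak_time_s = numeric(), amplitude_dff = numeric(),
                          fwhm_s = numeric())
    }
    attr(truth, "footprints") <- footprints

    # --- compose, displace, add noise ------------------------------------
    clean <- f0_t * (1 + dff_true)           # recycles f0_t down columns
    rm(dff_true)
    data <- array(clean, dim = c(T, ny, nx))
    rm(clean)

    n_art <- stats::rpois(1, cf$motion_artifact_rate)
    artifact_frames <- integer(0)
    if (n_art > 0) {
      artifact_frames <- sort(sample(2:(T - 1), min(n_art, T - 2)))
      for (fr in artifact_frames) {
        sh <- sample(c(-3:-1, 1:3), 2, replace = TRUE)
        frame <- data[fr, , , drop = FALSE]
        frame <- shift_array(frame, sh[1], 2L)
        frame <- shift_array(frame, sh[2], 3L)
        data[fr, , ] <- frame
      }
    }

    if (cf$noise_model == "gaussian") {
      if (cf$noise_sd > 0) {
        data <- data + stats::rnorm(length(data), sd = cf$noise_sd)
      }
    } else {
      data <- cf$gain * array(stats::rpois(length(data), data / cf$gain),
                              dim = dim(data))
      if (cf$read_sd > 0) {
        data <- data + stats::rnorm(length(data), sd = cf$read_sd)
      }
    }
    n_clamped <- sum(data < 0)
    data[data < 0] <- 0
    attr(data, "n_clamped") <- n_clamped
    attr(data, "artifact_frames") <- artifact_frames

    movie <- ca_movie(data, cf$pixel_size_um, cf$frame_interval_s)
    list(movie = movie, truth = truth)
  })
}
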
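#' Mean dF/F0 trace of an ROA
#'
#' @param dff a [compute_dff()] stack.
#' @param roa one element of a [grow_roas()] set (or any list with a
#'   `pixels` field of column-major pixel indices).
#' @return numeric vector: mean dF/F0 over the ROA's pixels, per frame.
#' @export
extract_roa_trace <- function(dff, roa) {
  stopifnot(inherits(dff, "dff_stack"))
  px <- roa$pixels
  d <- dim(dff$data)
  if (any(px < 1 | px > d[2] * d[3])) {
    stop("ROA pixels fall outside the frame", call. = FALSE)
  }
  m <- matrix(dff$data, nrow = d[1])
  rowMeans(m[, px, drop = FALSE])
}

#' Detect Ca2+ events in a dF/F0 trace
#'
#' Events are maximal suprathreshold excursions above
#' `baseline + threshold_k * sigma_noise`, where the baseline level and
#' noise sd are estimated from the trace's subthreshold samples by a short
#' iteration (median / sd of samples below the current threshold), so that
#' the events themselves do not inflate the noise estimate. Each excursion
#' yields one event: the amplitude is the trace value at the excursion
#' maximum, and the duration is the full width at half that maximum, with
#' linear interpolation between frames at the two half-maximum crossings.
#' Events whose half-maximum extent is cut by the recording edge report the
#' observed width and are flagged `truncated`.
#'
#' Because an ROA trace averages many pixels, its noise sd can be far below
#' any physiologically resolvable transient, and a pure `k * sigma` rule
#' then admits sub-percent dF/F0 excursions. Excursions whose amplitude is
#' below `min_amplitude_dff` are therefore discarded: transients of a slow
#' genetically encoded indicator below ~10% dF/F0 are not resolvable as
#' events in vivo. The floor is a config knob (set 0 to disable).
#'
#' A noiseless trace (zero subthreshold sd) falls back to an epsilon
#' threshold above baseline; a flat trace yields no events.
#'
#' @param trace numeric dF/F0 vector (finite).
#' @param frame_interval_s seconds per frame.
#' @param threshold_k detection threshold in noise sds (default 3).
#' @param min_amplitude_dff minimum event amplitude in dF/F0 units
#'   (default 0.1).
#' @param roa_id optional id copied into the result.
#' @return data frame with one row per event: `roa_id`, `onset_s`,
#'   `peak_time_s`, `amplitude_dff`, `fwhm_s`, `truncated`; the detection
#'   threshold is attached as `attr(, "threshold")`.
#' @export
detect_events <- function(trace, frame_interval_s, threshold_k = 3,
                          min_amplitude_dff = 0.1, roa_id = NA_integer_) {
  if (anyNA(trace) || any(!is.finite(trace))) {
    stop("`trace` must be finite", call. = FALSE)
  }
  stopifnot_scalar_pos(frame_interval_s, "frame_interval_s")
  T <- length(trace)
  empty <- data.frame(roa_id = integer(), onset_s = numeric(),
                      peak_time_s = numeric(), amplitude_dff = numeric(),
                      fwhm_s = numeric(), truncated = logical())

  base <- stats::median(trace)
  sig <- stats::mad(trace)
  if (!is.finite(sig)) sig <- 0
  for (i in 1:3) {
    thr <- base + threshold_k * sig
    sub <- trace <= thr
    if (sum(sub) < 3) break
    base <- stats::median(trace[sub])
    sig_new <- stats::sd(trace[sub])
    if (!is.finite(sig_new)) sig_new <- 0
    sig <- sig_new
  }
  if (sig <= 0) {
    rng <- diff(range(trace))
    if (rng == 0) {
      attr(empty, "threshold") <- base
      return(empty)
    }
    thr <- base + 1e-9 * rng
  } else {
    thr <- base + threshold_k * sig
  }

  above <- trace > thr
  if (!any(above)) {
    attr(empty, "threshold") <- thr
    return(empty)
  }
  rr <- rle(above)
  ends <- cumsum(rr$lengths)
  starts <- ends - rr$lengths + 1L
  runs <- cbind(starts[rr$values], ends[rr$values])

  cross_time <- function(i0, i1, level) {
    # linear interpolation of the crossing between frames i0 and i1
    f <- (level - trace[i0]) / (trace[i1] - trace[i0])
    (i0 - 1 + f * (i1 - i0)) * frame_interval_s
  }

  out <- lapply(seq_len(nrow(runs)), function(k) {
    a <- runs[k, 1]; b <- runs[k, 2]
    pk <- a + which.max(trace[a:b]) - 1L
    amp <- trace[pk]
    if (amp < min_amplitude_dff) return(NULL)
    half <- amp / 2
    # search outwards from the peak for the half-maximum crossings
    i <- pk; trunc_l <- FALSE
    while (i > 1 && trace[i - 1] >= half) i <- i - 1L
    t_left <- if (i == 1) { trunc_l <- trace[1] >= half; 0 }
              else cross_time(i - 1L, i, half)
    j <- pk; trunc_r <- FALSE
    while (j < T && trace[j + 1] >= half) j <- j + 1L
    t_right <- if (j == T) { trunc_r <- trace[T] >= half; (T - 1) * frame_interval_s }
               else cross_time(j + 1L, j, half)
    data.frame(roa_id = roa_id,
               onset_s = (a - 1) * frame_interval_s,
               peak_time_s = (pk - 1) * frame_interval_s,
               amplitude_dff = amp,
               fwhm_s = t_right - t_left,
               truncated = trunc_l || trunc_r)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- empty
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  out
}

#' Detect events in every ROA of a set
#'
#' @param dff a [compute_dff()] stack.
#' @param roa_set a [grow_roas()] result.
#' @param threshold_k detection threshold in noise sds.
#' @param min_amplitude_dff minimum event amplitude (dF/F0).
#' @return data frame of events across all ROAs (see [detect_events()]).
#' @export
detect_events_roaset <- function(dff, roa_set, threshold_k = 3,
                                 min_amplitude_dff = 0.1) {
  d <- dim(dff$data)
  m <- if (length(roa_set$roas)) matrix(dff$data, nrow = d[1]) else NULL
  evs <- lapply(roa_set$roas, function(r) {
    detect_events(rowMeans(m[, r$pixels, drop = FALSE]),
                  dff$frame_interval_s, threshold_k = threshold_k,
                  min_amplitude_dff = min_amplitude_dff, roa_id = r$roa_id)
  })
  out <- if (length(evs)) do.call(rbind, evs) else
    data.frame(roa_id = integer(), onset_s = numeric(),
               peak_time_s = numeric(), amplitude_dff = numeric(),
               fwhm_s = numeric(), truncated = logical())
  rownames(out) <- NULL
  out
}

#' Summarize a recording's ROAs and events
#'
#' Computes the per-recording summary metrics: signal density (events per
#' um^2 of field per minute), ROA density, per-ROA signal frequency (mean
#' over ROAs of events-in-ROA per minute), and means of ROA area, event
#' amplitude and event FWHM. The densities satisfy the exact conservation
#' identities `signal_density * fov_area * duration = n_events` and
#' `roa_density * fov_area * duration = n_roas`.
#'
#' @param roa_set a [grow_roas()] result (or list of ROAs).
#' @param events event data frame from [detect_events_roaset()].
#' @param fov_area_um2 field-of-view area (um^2).
#' @param duration_min recording duration (minutes).
#' @return one-row data frame with the metric columns plus `n_events`,
#'   `n_roas`, `fov_area_um2`, `duration_min`. With zero ROAs the densities
#'   are 0 and the per-ROA means `NA`.
#' @export
summarize_metrics <- function(roa_set, events, fov_area_um2, duration_min) {
  stopifnot_scalar_pos(fov_area_um2, "fov_area_um2")
  stopifnot_scalar_pos(duration_min, "duration_min")
  roas <- if (inherits(roa_set, "roa_set")) roa_set$roas else roa_set
  n_roas <- length(roas)
  n_events <- nrow(events)
  per_roa_freq <- if (n_roas > 0) {
    counts <- vapply(roas, function(r) {
      sum(events$roa_id == r$roa_id)
    }, numeric(1))
    mean(counts / duration_min)
  } else NA_real_
  data.frame(
    signal_density_per_um2_min = n_events / (fov_area_um2 * duration_min),
    roa_density_per_um2_min = n_roas / (fov_area_um2 * duration_min),
    per_roa_frequency_per_min = per_roa_freq,
    mean_roa_area_um2 = if (n_roas > 0) {
      mean(vapply(roas, `[[`, numeric(1), "area_um2"))
    } else NA_real_,
    mean_amplitude_dff = if (n_events > 0) mean(events$amplitude_dff) else NA_real_,
    mean_fwhm_s = if (n_events > 0) mean(events$fwhm_s) else NA_real_,
    n_events = n_events,
    n_roas = n_roas,
    fov_area_um2 = fov_area_um2,
    duration_min = duration_min
  )
}
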
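#' Match detected events to ground-truth events
#'
#' Greedy one-to-one matching between detected events and the generator's
#' ground truth: a detected event may match a true event when their peak
#' times differ by at most `max_peak_dt_s` and the detected event's ROA
#' overlaps the true footprint by at least `min_overlap` of the smaller of
#' the two pixel sets. Candidate pairs are consumed in order of increasing
#' peak-time distance.
#'
#' @param events detected events ([detect_events_roaset()] output).
#' @param roa_set the [grow_roas()] set the events came from.
#' @param truth ground-truth table from [make_movie()] (with its
#'   `footprints` attribute).
#' @param max_peak_dt_s peak-time tolerance (s).
#' @param min_overlap minimum pixel overlap fraction of the smaller set.
#' @return list with `matches` (data frame: detected event row, truth
#'   `event_id`, true/detected amplitude, FWHM, ROA vs footprint area and
#'   Jaccard overlap), `recall`, `precision`, and median relative errors
#'   `amplitude_rel_err`, `fwhm_rel_err`, `area_rel_err`.
#' @export
match_events <- function(events, roa_set, truth, max_peak_dt_s = 3,
                         min_overlap = 0.3) {
  footprints <- attr(truth, "footprints")
  n_det <- nrow(events)
  n_true <- nrow(truth)
  empty <- data.frame(det_row = integer(), event_id = integer(),
                      peak_dt_s = numeric(),
                      amplitude_true = numeric(), amplitude_det = numeric(),
                      fwhm_true = numeric(), fwhm_det = numeric(),
                      area_true = numeric(), area_det = numeric(),
                      jaccard = numeric())
  if (n_det == 0L || n_true == 0L) {
    return(list(matches = empty,
                recall = if (n_true == 0) NA_real_ else 0,
                precision = if (n_det == 0) NA_real_ else 0,
                amplitude_rel_err = NA_real_, fwhm_rel_err = NA_real_,
                area_rel_err = NA_real_))
  }
  roa_px <- lapply(roa_set$roas, `[[`, "pixels")
  roa_area <- vapply(roa_set$roas, `[[`, numeric(1), "area_um2")
  roa_of <- match(events$roa_id,
                  vapply(roa_set$roas, `[[`, integer(1), "roa_id"))

  pairs <- NULL
  for (i in seq_len(n_det)) {
    dt <- abs(events$peak_time_s[i] - truth$peak_time_s)
    cand <- which(dt <= max_peak_dt_s)
    if (!length(cand)) next
    px_d <- roa_px[[roa_of[i]]]
    for (j in cand) {
      px_t <- footprints[[truth$site_id[j]]]
      ov <- length(intersect(px_d, px_t))
      if (ov / min(length(px_d), length(px_t)) >= min_overlap) {
        pairs <- rbind(pairs, data.frame(
          det_row = i, event_id = truth$event_id[j], peak_dt_s = dt[j],
          jaccard = ov / length(union(px_d, px_t))))
      }
    }
  }
  if (is.null(pairs) || nrow(pairs) == 0L) {
    return(list(matches = empty, recall = 0, precision = 0,
                amplitude_rel_err = NA_real_, fwhm_rel_err = NA_real_,
                area_rel_err = NA_real_))
  }
  pairs <- pairs[order(pairs$peak_dt_s), , drop = FALSE]
  used_d <- logical(n_det); used_t <- logical(n_true)
  keep <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$det_row[k]
    j <- match(pairs$event_id[k], truth$event_id)
    if (!used_d[i] && !used_t[j]) {
      keep[k] <- TRUE
      used_d[i] <- TRUE; used_t[j] <- TRUE
    }
  }
  mm <- pairs[keep, , drop = FALSE]
  jt <- match(mm$event_id, truth$event_id)
  matches <- data.frame(
    det_row = mm$det_row,
    event_id = mm$event_id,
    peak_dt_s = mm$peak_dt_s,
    amplitude_true = truth$amplitude_dff[jt],
    amplitude_det = events$amplitude_dff[mm$det_row],
    fwhm_true = truth$fwhm_s[jt],
    fwhm_det = events$fwhm_s[mm$det_row],
    area_true = truth$area_um2[jt],
    area_det = roa_area[roa_of[mm$det_row]],
    jaccard = mm$jaccard
  )
  rel <- function(a, b) stats::median(abs(a - b) / b)
  list(
    matches = matches,
    recall = nrow(matches) / n_true,
    precision = nrow(matches) / n_det,
    amplitude_rel_err = rel(matches$amplitude_det, matches$amplitude_true),
    fwhm_rel_err = rel(matches$fwhm_det, matches$fwhm_true),
    area_rel_err = rel(matches$area_det, matches$area_true)
  )
}
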
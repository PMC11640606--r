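#' End-to-end detection configuration
#'
#' Collects every stage's parameters in one list so a run is fully
#' reproducible from its configuration echo. Unknown parameter names are
#' rejected.
#'
#' @param ... overrides of the defaults: `median_window_frames`, `denoiser`,
#'   `sigma_t_frames`, `sigma_s_px`, `order` (preprocessing);
#'   `f0_degree`, `robust_iterations`, `robust_k` (baseline);
#'   `neighborhood_px`, `noise_floor`, `corr_threshold`,
#'   `min_roa_area_um2`, `event_threshold_k` (detection).
#' @return list of class `detect_config`.
#' @export
detect_config <- function(...) {
  defaults <- list(
    median_window_frames = 3L,
    denoiser = "variance_stabilized_smoothing",
    sigma_t_frames = 0.75,
    sigma_s_px = 0,
    order = "median_first",
    f0_degree = 3L,
    robust_iterations = 2L,
    robust_k = 2,
    neighborhood_px = 2L,
    seed_smooth_px = 1.5,
    noise_floor = NULL,
    corr_threshold = 0.2,
    min_roa_area_um2 = 5,
    event_threshold_k = 3,
    min_amplitude_dff = 0.1
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown)) {
    stop("unknown detect_config parameter(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, dots, keep.null = TRUE)
  structure(cfg, class = "detect_config")
}

#' Run the full ROA detection pipeline on one recording
#'
#' Preprocesses the movie (temporal median filter + denoiser), fits the
#' per-pixel polynomial baseline, normalizes to dF/F0, computes the range
#' projection, finds seeds, grows ROAs by seed-anchored temporal
#' correlation, extracts per-ROA events, and summarizes the recording's
#' metrics. Fully deterministic given the movie and configuration.
#'
#' @param movie a [ca_movie()] or the path to a TIFF written by
#'   [write_movie_tiff()] (its JSON sidecar provides the calibration;
#'   a missing sidecar is an error, since the densities are unit-bearing).
#' @param config a [detect_config()].
#' @param out_dir optional directory: writes `events.csv`, `metrics.csv`
#'   (thresholds echoed in a comment header), `roa_labels.tif` (16-bit
#'   label map, 0 = background) and `provenance.json`.
#' @return list of class `roa_detection` with `metrics`, `events`,
#'   `roa_set`, `range_map`, `baseline`, `dff`, `config`.
#' @export
run_detect <- function(movie, config = detect_config(), out_dir = NULL) {
  if (is.character(movie)) movie <- read_movie_tiff(movie)
  stopifnot(inherits(movie, "ca_movie"), inherits(config, "detect_config"))

  pp_cfg <- preprocess_config(
    median_window_frames = config$median_window_frames,
    denoiser = config$denoiser,
    sigma_t_frames = config$sigma_t_frames,
    sigma_s_px = config$sigma_s_px,
    order = config$order
  )
  fov_um2 <- fov_area_um2(movie)
  dur_min <- dim(movie$data)[1] * movie$frame_interval_s / 60
  pp <- preprocess_movie(movie, pp_cfg)
  baseline <- fit_f0(pp, degree = config$f0_degree,
                     robust_iterations = config$robust_iterations,
                     robust_k = config$robust_k)
  dff <- compute_dff(pp, baseline)
  rm(pp)                                # the preprocessed stack is no longer needed
  rmap <- range_projection(dff)
  seeds <- find_seeds(rmap, neighborhood_px = config$neighborhood_px,
                      noise_floor = config$noise_floor,
                      smooth_sigma_px = config$seed_smooth_px)
  roa_set <- grow_roas(dff, seeds, corr_threshold = config$corr_threshold,
                       min_roa_area_um2 = config$min_roa_area_um2)
  events <- detect_events_roaset(dff, roa_set,
                                 threshold_k = config$event_threshold_k,
                                 min_amplitude_dff = config$min_amplitude_dff)
  metrics <- summarize_metrics(roa_set, events, fov_area_um2 = fov_um2,
                               duration_min = dur_min)

  res <- structure(
    list(metrics = metrics, events = events, roa_set = roa_set,
         range_map = rmap, baseline = baseline, dff = dff,
         config = config, seeds = seeds),
    class = "roa_detection"
  )
  if (!is.null(out_dir)) write_detection(res, out_dir)
  res
}

#' @export
print.roa_detection <- function(x, ...) {
  cat(sprintf(
    "<roa_detection> %d ROA(s), %d event(s) | signal density %.4g /um^2/min\n",
    x$metrics$n_roas, x$metrics$n_events,
    x$metrics$signal_density_per_um2_min))
  invisible(x)
}

# Write the artifacts of one detection run: events/metrics CSVs (all
# thresholds echoed as comment headers for provenance), the ROA label map as
# 16-bit TIFF, and a machine-readable provenance block.
write_detection <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- unclass(res$config)
  hdr <- paste0("# ", paste(names(cfg),
                            vapply(cfg, function(v)
                              if (is.null(v)) "auto" else format(v),
                              character(1)),
                            sep = "=", collapse = " "))
  ev_path <- file.path(out_dir, "events.csv")
  writeLines(hdr, ev_path)
  suppressWarnings(utils::write.table(
    res$events, ev_path, append = TRUE, sep = ",",
    row.names = FALSE, col.names = TRUE, qmethod = "double"))
  mt_path <- file.path(out_dir, "metrics.csv")
  writeLines(hdr, mt_path)
  suppressWarnings(utils::write.table(
    res$metrics, mt_path, append = TRUE, sep = ",",
    row.names = FALSE, col.names = TRUE, qmethod = "double"))
  lbl <- res$roa_set$label_map
  tiff::writeTIFF(lbl / 65535, file.path(out_dir, "roa_labels.tif"),
                  bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(
    list(config = cfg, n_roas = res$metrics$n_roas,
         n_events = res$metrics$n_events,
         noise_floor_used = attr(res$seeds, "noise_floor"),
         package_version = as.character(utils::packageVersion("roaevents"))),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(out_dir)
}

#' Compare recording metrics between groups
#'
#' The statistical comparison layer over per-recording metric tables:
#' for every metric column, measurements are optionally collapsed to one
#' value per animal, the Shapiro-Wilk gate selects the branch, and the two
#' groups are compared ([two_group_test()]). When a reference (untreated)
#' table is supplied, per-observation fold changes against the matching
#' reference group's mean are additionally tested against unity
#' ([one_sample_vs_unity()]).
#'
#' @param metrics data frame of per-recording metrics with a `group` column
#'   (exactly 2 levels) and optionally an `animal` column.
#' @param metric_cols character vector of metric columns to test (default:
#'   the standard summary metrics present in the table).
#' @param reference optional data frame with the same structure from the
#'   untreated condition; its `group` levels must match.
#' @param per_animal collapse to per-animal means first (default `TRUE`
#'   when an `animal` column is present).
#' @return data frame of test results (one row per metric and test).
#' @export
run_compare <- function(metrics, metric_cols = NULL, reference = NULL,
                        per_animal = "animal" %in% names(metrics)) {
  if (!"group" %in% names(metrics)) {
    stop("`metrics` must have a `group` column", call. = FALSE)
  }
  groups <- unique(as.character(metrics$group))
  if (length(groups) != 2) {
    stop("`run_compare` expects exactly 2 groups, got: ",
         paste(groups, collapse = ", "), call. = FALSE)
  }
  if (is.null(metric_cols)) {
    metric_cols <- intersect(
      c("signal_density_per_um2_min", "roa_density_per_um2_min",
        "per_roa_frequency_per_min", "mean_roa_area_um2",
        "mean_amplitude_dff", "mean_fwhm_s"),
      names(metrics))
  }
  missing_cols <- setdiff(metric_cols, names(metrics))
  if (length(missing_cols)) {
    stop("metric column(s) not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(reference)) {
    ref_groups <- unique(as.character(reference$group))
    bad <- setdiff(groups, ref_groups)
    if (length(bad)) {
      stop("reference table lacks group label(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }

  take <- function(df, g, col) {
    sub <- df[df$group == g, , drop = FALSE]
    if (per_animal && "animal" %in% names(df)) {
      sub <- aggregate_per_animal(sub, col, "animal")
    }
    sub[[col]][!is.na(sub[[col]])]
  }

  out <- lapply(metric_cols, function(col) {
    a <- take(metrics, groups[1], col)
    b <- take(metrics, groups[2], col)
    rows <- two_group_test(a, b,
                           comparison = sprintf("%s: %s vs %s",
                                                col, groups[1], groups[2]))
    rows$metric <- col
    if (!is.null(reference)) {
      for (g in groups) {
        ref_mean <- mean(take(reference, g, col))
        fc <- fold_change(take(metrics, g, col), ref_mean)
        os <- one_sample_vs_unity(fc)
        rows <- rbind(rows, data.frame(
          comparison = sprintf("%s: %s fold change vs 1", col, g),
          test = os$test, statistic = os$statistic, df = os$df,
          p_value = os$p_value, branch = "parametric", metric = col))
      }
    }
    rows
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
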
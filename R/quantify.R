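#' Cell density per cubic millimeter
#'
#' Converts a cell count over a counting volume (field-of-view area times
#' section or stack thickness) into a density in mm^-3. Vectorized over
#' counts.
#'
#' @param count non-negative cell count(s).
#' @param fov_area_um2 field-of-view area (um^2).
#' @param thickness_um counting depth (um): the imaged stack depth when
#'   known, otherwise the section thickness.
#' @return density in cells per mm^3.
#' @export
cell_density <- function(count, fov_area_um2, thickness_um) {
  stopifnot_scalar_pos(fov_area_um2, "fov_area_um2")
  stopifnot_scalar_pos(thickness_um, "thickness_um")
  if (any(count < 0)) stop("`count` must be >= 0", call. = FALSE)
  count / (fov_area_um2 * thickness_um) * 1e9
}

#' Lineage fractions and differentiation ratio of a census table
#'
#' Adds, per field of view, the fractions of recombined OPCs
#' (`PDGFRa+GFP+ / GFP+`) and recombined mature oligodendrocytes
#' (`MyRF+GFP+ / GFP+`) among recombined cells, and the differentiation
#' ratio `MyRF+GFP+ / PDGFRa+GFP+` (mature oligodendrocytes produced per
#' recombined OPC). Zero denominators give `NA` with a warning, never a
#' silent 0.
#'
#' @param table a census data frame with columns `gfp_pos`, `pdgfra_gfp`,
#'   `myrf_gfp` (e.g. from [make_census_table()]).
#' @return the table with columns `frac_pdgfra`, `frac_myrf`,
#'   `differentiation_ratio` appended.
#' @export
lineage_fractions <- function(table) {
  need <- c("gfp_pos", "pdgfra_gfp", "myrf_gfp")
  if (!all(need %in% names(table))) {
    stop("census table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(table$pdgfra_gfp + table$myrf_gfp > table$gfp_pos)) {
    stop("marker-positive counts exceed GFP+ totals", call. = FALSE)
  }
  gfp <- table$gfp_pos
  frac_pa <- ifelse(gfp > 0, table$pdgfra_gfp / gfp, NA_real_)
  frac_my <- ifelse(gfp > 0, table$myrf_gfp / gfp, NA_real_)
  ratio <- ifelse(table$pdgfra_gfp > 0,
                  table$myrf_gfp / table$pdgfra_gfp, NA_real_)
  if (any(gfp == 0)) {
    warning("FOV(s) with zero GFP+ cells: fractions set to NA", call. = FALSE)
  }
  if (any(table$pdgfra_gfp == 0)) {
    warning("FOV(s) with zero PDGFRa+GFP+ cells: ratio set to NA",
            call. = FALSE)
  }
  table$frac_pdgfra <- frac_pa
  table$frac_myrf <- frac_my
  table$differentiation_ratio <- ratio
  table
}

#' Fold change against an untreated reference mean
#'
#' Divides each treated value by its group's untreated reference mean, the
#' convention used for reporting treatment effects relative to the
#' untreated condition (fold change = 1 means no change).
#'
#' @param treated_values numeric vector of treated measurements.
#' @param untreated_reference_mean positive scalar: mean of the matching
#'   untreated group.
#' @return numeric vector of per-observation fold changes.
#' @export
fold_change <- function(treated_values, untreated_reference_mean) {
  if (!is.numeric(untreated_reference_mean) ||
      length(untreated_reference_mean) != 1L ||
      !is.finite(untreated_reference_mean) ||
      untreated_reference_mean <= 0) {
    stop("`untreated_reference_mean` must be a positive scalar",
         call. = FALSE)
  }
  treated_values / untreated_reference_mean
}

#' Mean intensity and coverage of a single-channel image
#'
#' Returns the mean of the raw intensities over the analysis region and the
#' coverage: the percentage of region pixels above threshold. The default
#' threshold rule is Otsu's method computed on the analysis region; the
#' threshold used is always echoed in the result.
#'
#' @param image numeric matrix.
#' @param threshold_rule `"otsu"` or `"fixed"`.
#' @param threshold numeric threshold when `threshold_rule = "fixed"`.
#' @param region_mask optional logical matrix restricting the analysis
#'   region (default: whole image).
#' @return list with `mean_intensity`, `coverage_pct`, `threshold`.
#' @export
mbp_intensity_coverage <- function(image, threshold_rule = c("otsu", "fixed"),
                                   threshold = NULL, region_mask = NULL) {
  threshold_rule <- match.arg(threshold_rule)
  if (!is.matrix(image)) stop("`image` must be a matrix", call. = FALSE)
  if (is.null(region_mask)) region_mask <- matrix(TRUE, nrow(image), ncol(image))
  vals <- image[region_mask]
  if (length(vals) == 0L) stop("empty analysis region", call. = FALSE)
  thr <- if (threshold_rule == "fixed") {
    if (is.null(threshold)) stop("`threshold` required for rule 'fixed'",
                                 call. = FALSE)
    threshold
  } else {
    otsu_threshold(vals)
  }
  list(mean_intensity = mean(vals),
       coverage_pct = 100 * mean(vals > thr),
       threshold = thr)
}

# Otsu's threshold on raw intensity values (EBImage::otsu expects [0, 1]
# images, so values are rescaled and the threshold mapped back).
otsu_threshold <- function(vals) {
  rng <- range(vals)
  if (diff(rng) == 0) return(rng[1])
  scaled <- (vals - rng[1]) / diff(rng)
  thr01 <- EBImage::otsu(matrix(scaled, nrow = 1), range = c(0, 1),
                         levels = 256)
  rng[1] + thr01 * diff(rng)
}

#' Per-axon relative myelin (MBP) area
#'
#' For each axon location, the myelin channel is thresholded and the
#' connected MBP component enclosing the axon identified; the measured
#' quantity is the full filled area inside the outer MBP boundary (the
#' myelin ring plus the enclosed lumen) divided by the
#' neurofilament-positive area enclosed within it, giving ratios >= 1 when
#' myelin encloses the axon. An `"annulus"` mode (ring area only) is
#' available behind a flag. Axons whose MBP ring does not enclose them
#' (hole filling adds no lumen containing the axon) are flagged
#' unmeasurable.
#'
#' @param mbp,nf numeric matrices: myelin and neurofilament channels.
#' @param axon_centers integer matrix or data frame with columns `y`, `x`
#'   (one row per axon); default: the frame center (single-axon images).
#' @param pixel_size_um pixel size (um), default 1 (areas then in px^2).
#' @param threshold_rule `"otsu"` or `"fixed"` (with `mbp_threshold`,
#'   `nf_threshold`).
#' @param mbp_threshold,nf_threshold fixed thresholds.
#' @param mode `"filled"` (default: filled outer boundary, axon included)
#'   or `"annulus"` (MBP ring area only).
#' @return data frame with one row per axon: `axon_id`,
#'   `mbp_delimited_area_um2`, `nf_area_um2`, `relative_mbp_area`,
#'   `axon_diameter_um`, `measurable`.
#' @export
per_axon_relative_mbp_area <- function(mbp, nf, axon_centers = NULL,
                                       pixel_size_um = 1,
                                       threshold_rule = c("otsu", "fixed"),
                                       mbp_threshold = NULL,
                                       nf_threshold = NULL,
                                       mode = c("filled", "annulus")) {
  threshold_rule <- match.arg(threshold_rule)
  mode <- match.arg(mode)
  stopifnot(is.matrix(mbp), is.matrix(nf), identical(dim(mbp), dim(nf)))
  if (is.null(axon_centers)) {
    axon_centers <- data.frame(y = round((nrow(mbp) + 1) / 2),
                               x = round((ncol(mbp) + 1) / 2))
  }
  axon_centers <- as.data.frame(axon_centers)

  thr_m <- if (threshold_rule == "fixed") mbp_threshold else
    otsu_threshold(as.vector(mbp))
  thr_n <- if (threshold_rule == "fixed") nf_threshold else
    otsu_threshold(as.vector(nf))
  mbp_mask <- mbp > thr_m
  nf_mask <- nf > thr_n

  labels <- EBImage::bwlabel(mbp_mask * 1)
  out <- lapply(seq_len(nrow(axon_centers)), function(i) {
    cy <- axon_centers$y[i]; cx <- axon_centers$x[i]
    row <- data.frame(axon_id = i, mbp_delimited_area_um2 = NA_real_,
                      nf_area_um2 = NA_real_, relative_mbp_area = NA_real_,
                      axon_diameter_um = NA_real_, measurable = FALSE)
    # find the MBP component whose hole-filled extent contains the axon
    comp_ids <- sort(unique(labels[labels > 0]))
    enclosing <- NA_integer_
    filled <- NULL
    for (k in comp_ids) {
      comp <- labels == k
      fk <- EBImage::fillHull(comp * 1) > 0
      if (fk[cy, cx] && !comp[cy, cx]) { enclosing <- k; filled <- fk; break }
    }
    if (is.na(enclosing)) return(row)   # open or absent ring: unmeasurable
    comp <- labels == enclosing
    outer_area_px <- if (mode == "filled") sum(filled) else sum(comp)
    # NF+ area enclosed within the MBP boundary, component containing the axon
    lumen_nf <- nf_mask & filled
    nf_labels <- EBImage::bwlabel(lumen_nf * 1)
    if (nf_labels[cy, cx] == 0) return(row)
    nf_area_px <- sum(nf_labels == nf_labels[cy, cx])
    row$mbp_delimited_area_um2 <- outer_area_px * pixel_size_um^2
    row$nf_area_um2 <- nf_area_px * pixel_size_um^2
    row$relative_mbp_area <- outer_area_px / nf_area_px
    row$axon_diameter_um <- 2 * sqrt(nf_area_px / pi) * pixel_size_um
    row$measurable <- TRUE
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
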
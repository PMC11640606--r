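#' Generate a synthetic marker co-expression census table
#'
#' Emulates per-field-of-view cell counts from lineage-tracing
#' immunohistochemistry: recombined (GFP+) cells classified as OPCs
#' (PDGFRa+GFP+), mature oligodendrocytes (MyRF+GFP+) or neither, plus a
#' proliferation marker (Ki67+GFP+) and non-recombined (GFP-) counterparts.
#' GFP+ totals are Poisson; the PDGFRa/MyRF split is multinomial within each
#' FOV, which guarantees `PDGFRa+GFP+ + MyRF+GFP+ <= GFP+` exactly; Ki67 is
#' an independent binomial among GFP+ cells.
#'
#' @param group_sizes named integer vector: number of FOVs per group,
#'   e.g. `c(ctrl = 12, cKD = 12)`.
#' @param marker_rates either a single list with elements `pdgfra`, `myrf`,
#'   `ki67` (rates in `[0, 1]`, `pdgfra + myrf <= 1`) applied to all groups,
#'   or a named list of such lists, one per group.
#' @param rng_seed integer seed.
#' @param mean_gfp,mean_gfp_neg Poisson means of recombined and
#'   non-recombined cell totals per FOV.
#' @param fov_area_um2 field-of-view area (um^2).
#' @param thickness_um section thickness (um); 40 um transversal sections by
#'   default.
#' @param region tissue region label.
#'
#' @return data frame of class `census_table`, one row per FOV, with count
#'   columns `gfp_pos`, `pdgfra_gfp`, `myrf_gfp`, `ki67_gfp`, `gfp_neg`,
#'   `pdgfra_gfpneg`, `myrf_gfpneg`, `ki67_gfpneg` and the geometry columns.
#' @export
make_census_table <- function(group_sizes, marker_rates, rng_seed = 1L,
                              mean_gfp = 100, mean_gfp_neg = 60,
                              fov_area_um2 = 500 * 500, thickness_um = 40,
                              region = "white") {
  if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes)))) {
    stop("`group_sizes` must be a named vector", call. = FALSE)
  }
  if (!is.list(marker_rates)) stop("`marker_rates` must be a list", call. = FALSE)
  per_group <- all(names(group_sizes) %in% names(marker_rates)) &&
    all(vapply(marker_rates, is.list, logical(1)))
  check_rates <- function(r) {
    vals <- unlist(r[c("pdgfra", "myrf", "ki67")])
    if (length(vals) != 3L || any(vals < 0) || any(vals > 1)) {
      stop("marker rates must lie in [0, 1]", call. = FALSE)
    }
    if (r$pdgfra + r$myrf > 1) {
      stop("pdgfra + myrf rates must not exceed 1", call. = FALSE)
    }
  }
  if (per_group) lapply(marker_rates, check_rates) else check_rates(marker_rates)

  with_local_seed(rng_seed, {
    rows <- lapply(names(group_sizes), function(g) {
      n <- group_sizes[[g]]
      r <- if (per_group) marker_rates[[g]] else marker_rates
      gfp <- stats::rpois(n, mean_gfp)
      split <- t(vapply(gfp, function(k) {
        stats::rmultinom(1, k, c(r$pdgfra, r$myrf,
                                 max(0, 1 - r$pdgfra - r$myrf)))[, 1]
      }, integer(3)))
      gfpn <- stats::rpois(n, mean_gfp_neg)
      splitn <- t(vapply(gfpn, function(k) {
        stats::rmultinom(1, k, c(r$pdgfra, r$myrf,
                                 max(0, 1 - r$pdgfra - r$myrf)))[, 1]
      }, integer(3)))
      data.frame(
        group = g, fov = seq_len(n),
        gfp_pos = gfp,
        pdgfra_gfp = split[, 1], myrf_gfp = split[, 2],
        ki67_gfp = stats::rbinom(n, gfp, r$ki67),
        gfp_neg = gfpn,
        pdgfra_gfpneg = splitn[, 1], myrf_gfpneg = splitn[, 2],
        ki67_gfpneg = stats::rbinom(n, gfpn, r$ki67),
        fov_area_um2 = fov_area_um2, thickness_um = thickness_um,
        region = region,
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    class(out) <- c("census_table", "data.frame")
    out
  })
}

#' Generate a synthetic myelinated-axon image pair
#'
#' Produces a two-channel image of one myelinated axon cross-section: the
#' myelin (MBP) channel is an annulus between `axon_radius_px` and
#' `outer_radius_px`, the neurofilament (NF) channel a disc of radius
#' `axon_radius_px`, both centered in the frame. The true relative myelin
#' area — the filled region enclosed by the MBP ring divided by the NF+
#' area — is `outer_radius_px^2 / axon_radius_px^2` analytically.
#'
#' @param outer_radius_px outer myelin radius (px).
#' @param axon_radius_px axon (inner) radius (px); must be `< outer`.
#' @param image_size frame edge length (px).
#' @param noise_sd Gaussian noise sd added to both channels (clamped at 0).
#' @param mbp_level,nf_level foreground intensity of each channel.
#' @param rng_seed seed for the noise (ignored when `noise_sd = 0`).
#'
#' @return list with `mbp` and `nf` matrices (`image_size x image_size`) and
#'   `true_ratio = outer_radius_px^2 / axon_radius_px^2`.
#' @export
make_axon_image <- function(outer_radius_px, axon_radius_px,
                            image_size = 64L, noise_sd = 0,
                            mbp_level = 1, nf_level = 1, rng_seed = 1L) {
  stopifnot_scalar_pos(outer_radius_px, "outer_radius_px")
  stopifnot_scalar_pos(axon_radius_px, "axon_radius_px")
  if (axon_radius_px >= outer_radius_px) {
    stop("`axon_radius_px` must be smaller than `outer_radius_px`",
         call. = FALSE)
  }
  if (2 * outer_radius_px + 4 > image_size) {
    stop("radii exceed the frame; increase `image_size`", call. = FALSE)
  }
  ctr <- (image_size + 1) / 2
  d <- sqrt(outer((seq_len(image_size) - ctr)^2,
                  (seq_len(image_size) - ctr)^2, `+`))
  mbp <- mbp_level * (d > axon_radius_px & d <= outer_radius_px)
  nf <- nf_level * (d <= axon_radius_px)
  if (noise_sd > 0) {
    with_local_seed(rng_seed, {
      mbp <- pmax(mbp + stats::rnorm(length(mbp), sd = noise_sd), 0)
      nf <- pmax(nf + stats::rnorm(length(nf), sd = noise_sd), 0)
      dim(mbp) <- dim(nf) <- c(image_size, image_size)
    })
  }
  list(mbp = mbp, nf = nf,
       true_ratio = outer_radius_px^2 / axon_radius_px^2)
}
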
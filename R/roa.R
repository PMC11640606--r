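#' Find seed points on the range projection
#'
#' Seeds are strict local maxima of the range map within a Chebyshev
#' neighborhood of radius `neighborhood_px`, above a noise floor. Ties on
#' plateaus are broken deterministically: among equal-valued neighbors the
#' pixel earliest in column-major order wins, so exactly one seed is
#' reported per plateau. The default noise floor is
#' `median(range) + 3 * mad(range)`, a robust bound on the range a pure-noise
#' pixel attains over the recording (active pixels barely move the median
#' or the MAD).
#'
#' Before maxima are picked, the map is lightly Gaussian-smoothed
#' (`smooth_sigma_px`), so that a spatially extended active domain — whose
#' raw range values are a plateau plus noise — contributes one seed rather
#' than one per noise wiggle. Region growing itself uses the raw traces;
#' smoothing only stabilizes seed placement.
#'
#' @param range_map a [range_projection()] map.
#' @param neighborhood_px Chebyshev radius (>= 1) of the local-maximum and
#'   deduplication neighborhood.
#' @param noise_floor numeric threshold on the (smoothed) range value;
#'   `NULL` uses the robust default above.
#' @param smooth_sigma_px Gaussian sd (px) of the pre-seeding smoothing of
#'   the range map (0 disables).
#' @return data frame with one row per seed: `y`, `x`, `range_value`,
#'   ordered by decreasing range value (row-major on ties); the noise floor
#'   used is attached as `attr(, "noise_floor")`. A flat map yields zero
#'   rows.
#' @export
find_seeds <- function(range_map, neighborhood_px = 2L, noise_floor = NULL,
                       smooth_sigma_px = 1.5) {
  stopifnot(inherits(range_map, "range_map"))
  if (neighborhood_px < 1) stop("`neighborhood_px` must be >= 1", call. = FALSE)
  rm_ <- range_map$data
  ny <- nrow(rm_); nx <- ncol(rm_)
  if (smooth_sigma_px > 0) {
    arr <- array(rm_, dim = c(1L, ny, nx))
    arr[is.na(arr)] <- stats::median(rm_, na.rm = TRUE)
    arr <- gaussian_smooth_axis(arr, smooth_sigma_px, 2L)
    arr <- gaussian_smooth_axis(arr, smooth_sigma_px, 3L)
    sm <- matrix(arr, ny, nx)
    sm[is.na(rm_)] <- NA_real_
  } else {
    sm <- rm_
  }
  if (is.null(noise_floor)) {
    noise_floor <- stats::median(sm, na.rm = TRUE) +
      3 * stats::mad(sm, na.rm = TRUE)
  }
  v <- sm
  v[is.na(v)] <- -Inf
  keep <- v > noise_floor
  r <- as.integer(neighborhood_px)
  shift2 <- function(m, dy, dx) {
    # shift with -Inf padding so borders never lose to out-of-frame pixels
    out <- matrix(-Inf, ny, nx)
    ys <- seq_len(ny) - dy; xs <- seq_len(nx) - dx
    oky <- ys >= 1 & ys <= ny; okx <- xs >= 1 & xs <= nx
    out[oky, okx] <- m[ys[oky], xs[okx]]
    out
  }
  for (dx in -r:r) {
    for (dy in -r:r) {
      if (dx == 0 && dy == 0) next
      nb <- shift2(v, dy, dx)
      later <- (dx > 0) || (dx == 0 && dy > 0)   # neighbor after us, col-major
      keep <- keep & if (later) v >= nb else v > nb
      if (!any(keep)) break
    }
  }
  idx <- which(keep)
  if (length(idx) == 0L) {
    out <- data.frame(y = integer(), x = integer(), range_value = numeric())
  } else {
    yx <- pixel_yx(idx, ny)
    out <- data.frame(y = yx[, "y"], x = yx[, "x"], range_value = v[idx])
    out <- out[order(-out$range_value, idx), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "noise_floor") <- noise_floor
  out
}

#' Grow regions of activity from seeds by temporal correlation
#'
#' All seeds grow simultaneously, in lockstep rounds, over 8-connected
#' frontiers: in each round every unassigned pixel adjacent to at least one
#' region is evaluated, and it joins the adjacent region whose *seed pixel
#' trace* it correlates with most (Pearson, over all frames), provided that
#' correlation is at least `corr_threshold`. Correlation is anchored on the
#' seed trace (not the evolving region mean) so the threshold is a fixed,
#' post-hoc checkable criterion for every member pixel. Competing claims are
#' resolved by the larger correlation, then by higher seed range value, then
#' by seed order (row-major), so growth is deterministic. Regions are
#' disjoint by construction.
#'
#' After growth, spatially adjacent regions are merged when *every* pixel of
#' the lower-priority region also correlates at or above `corr_threshold`
#' with the higher-priority region's seed: an extended active domain can
#' seed more than one local maximum, and by the growth criterion itself such
#' fragments are one microdomain. The merged region keeps the
#' higher-range-value seed, so the per-pixel correlation bound against the
#' (single) retained seed holds for every member pixel of every reported
#' ROA. Regions smaller than `min_roa_area_um2` are discarded last.
#'
#' @param dff a [compute_dff()] stack.
#' @param seeds data frame from [find_seeds()] on the same stack.
#' @param corr_threshold temporal correlation threshold in `[0, 1]`
#'   (default 0.2).
#' @param min_roa_area_um2 minimum reported ROA area in um^2 (default 5).
#' @return object of class `roa_set`: list of ROAs (`roa_id`, `pixels`
#'   (column-major indices), `seed` (y, x), `seed_range`, `area_um2`),
#'   plus the integer `label_map` (Y x X; 0 = background) and the thresholds
#'   used.
#' @export
grow_roas <- function(dff, seeds, corr_threshold = 0.2,
                      min_roa_area_um2 = 5) {
  stopifnot(inherits(dff, "dff_stack"))
  if (corr_threshold < 0 || corr_threshold > 1) {
    stop("`corr_threshold` must lie in [0, 1]", call. = FALSE)
  }
  stopifnot_scalar_pos(min_roa_area_um2, "min_roa_area_um2")
  d <- dim(dff$data)
  T <- d[1]; ny <- d[2]; nx <- d[3]
  P <- ny * nx
  empty <- structure(list(roas = list(),
                          label_map = matrix(0L, ny, nx),
                          corr_threshold = corr_threshold,
                          min_roa_area_um2 = min_roa_area_um2,
                          pixel_size_um = dff$pixel_size_um),
                     class = "roa_set")
  if (nrow(seeds) == 0L) return(empty)

  m <- matrix(dff$data, nrow = T)             # T x P
  mu <- colMeans(m)
  sdv <- sqrt(pmax(colMeans(m^2) - mu^2, 0) * T / (T - 1))
  usable <- is.finite(sdv) & sdv > 0

  # seeds ordered by range desc (then row-major); index = priority
  K <- nrow(seeds)
  seed_idx <- pixel_index(as.integer(seeds$y), as.integer(seeds$x), ny)
  seed_ctr <- m[, seed_idx, drop = FALSE]
  seed_ctr <- sweep(seed_ctr, 2, mu[seed_idx])
  seed_sd <- sdv[seed_idx]

  label <- integer(P)
  ok_seed <- usable[seed_idx]
  label[seed_idx[ok_seed]] <- which(ok_seed)

  offs <- expand.grid(dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dy == 0 & offs$dx == 0), ]
  off_lin <- offs$dy + offs$dx * ny

  yx_all <- pixel_yx(seq_len(P), ny)
  frontier_of <- function(active_px) {
    # candidate (pixel, region) pairs from the 8-neighborhood of active_px
    cand_p <- integer(0); cand_r <- integer(0)
    ay <- yx_all[active_px, 1L]; ax <- yx_all[active_px, 2L]
    for (i in seq_len(nrow(offs))) {
      yy <- ay + offs$dy[i]; xx <- ax + offs$dx[i]
      okb <- yy >= 1L & yy <= ny & xx >= 1L & xx <= nx
      if (!any(okb)) next
      np <- pixel_index(yy[okb], xx[okb], ny)
      src <- active_px[okb]
      sel <- label[np] == 0L & usable[np]
      if (any(sel)) {
        cand_p <- c(cand_p, np[sel])
        cand_r <- c(cand_r, label[src[sel]])
      }
    }
    if (length(cand_p)) unique(data.frame(p = cand_p, r = cand_r))
    else data.frame(p = integer(), r = integer())
  }

  active <- seed_idx[ok_seed]
  repeat {
    cand <- frontier_of(active)
    if (nrow(cand) == 0L) break
    # correlation of each candidate pixel with its candidate region's seed
    rho <- numeric(nrow(cand))
    for (k in unique(cand$r)) {
      rows <- which(cand$r == k)
      px <- cand$p[rows]
      # seed trace is centered, so crossprod needs no candidate centering
      cov <- as.vector(crossprod(m[, px, drop = FALSE], seed_ctr[, k])) / (T - 1)
      rho[rows] <- cov / (sdv[px] * seed_sd[k])
    }
    cand$rho <- rho
    cand <- cand[is.finite(cand$rho) & cand$rho >= corr_threshold, ,
                 drop = FALSE]
    if (nrow(cand) == 0L) break
    # best region per pixel: max correlation, then seed priority (lower = wins)
    ord <- order(cand$p, -cand$rho, cand$r)
    cand <- cand[ord, , drop = FALSE]
    cand <- cand[!duplicated(cand$p), , drop = FALSE]
    label[cand$p] <- cand$r
    active <- cand$p
  }

  # --- merge fragments of one microdomain --------------------------------
  # region k is absorbed into a higher-priority adjacent region j when all
  # of k's pixels correlate >= threshold with j's seed, so the per-pixel
  # bound against the retained seed is preserved exactly
  corr_with_seed <- function(px, k) {
    cov <- as.vector(crossprod(m[, px, drop = FALSE], seed_ctr[, k])) / (T - 1)
    cov / (sdv[px] * seed_sd[k])
  }
  owner <- seq_len(K)                       # current region of each seed
  repeat {
    changed <- FALSE
    for (k in rev(seq_len(K))) {            # lowest priority first
      if (owner[k] != k) next
      px_k <- which(label == k)
      if (!length(px_k)) next
      # adjacent region labels of higher priority
      nb <- unique(unlist(lapply(off_lin, function(o) {
        q <- px_k + o
        q <- q[q >= 1 & q <= P]
        # guard against row wrap-around on the frame edge
        ok <- abs(yx_all[q, 1L] - yx_all[pmin(pmax(q - o, 1L), P), 1L]) <= 1
        label[q[ok]]
      })))
      nb <- nb[nb != 0L & nb != k & nb < k]
      for (j in sort(nb)) {
        if (owner[j] != j) next
        rho_k <- corr_with_seed(px_k, j)
        if (all(is.finite(rho_k)) && all(rho_k >= corr_threshold)) {
          label[px_k] <- j
          owner[k] <- j
          changed <- TRUE
          break
        }
      }
    }
    if (!changed) break
  }

  min_px <- min_roa_area_um2 / dff$pixel_size_um^2
  roas <- list()
  label_map <- integer(P)
  next_id <- 0L
  for (k in seq_len(K)) {
    px <- which(label == k)
    if (length(px) == 0L || length(px) < min_px) next
    next_id <- next_id + 1L
    label_map[px] <- next_id
    roas[[next_id]] <- list(
      roa_id = next_id,
      pixels = px,
      seed = c(y = as.integer(seeds$y[k]), x = as.integer(seeds$x[k])),
      seed_range = seeds$range_value[k],
      area_um2 = length(px) * dff$pixel_size_um^2
    )
  }
  structure(list(roas = roas,
                 label_map = matrix(label_map, ny, nx),
                 corr_threshold = corr_threshold,
                 min_roa_area_um2 = min_roa_area_um2,
                 pixel_size_um = dff$pixel_size_um),
            class = "roa_set")
}

#' @export
print.roa_set <- function(x, ...) {
  n <- length(x$roas)
  cat(sprintf(
    "<roa_set> %d ROA(s) | min area %.3g um^2 | corr threshold %.3g\n",
    n, x$min_roa_area_um2, x$corr_threshold))
  invisible(x)
}

#' Per-pixel seed correlations of a grown ROA set
#'
#' Recomputes, for every member pixel of every ROA, the Pearson correlation
#' of its dF/F0 trace with its seed's trace — the post-hoc compliance check
#' for the growth criterion.
#'
#' @param dff the [compute_dff()] stack the set was grown on.
#' @param roa_set a [grow_roas()] result.
#' @return data frame with `roa_id`, `pixel`, `correlation`.
#' @export
roa_seed_correlations <- function(dff, roa_set) {
  d <- dim(dff$data)
  if (length(roa_set$roas) == 0L) {
    return(data.frame(roa_id = integer(), pixel = integer(),
                      correlation = numeric()))
  }
  m <- matrix(dff$data, nrow = d[1])
  out <- lapply(roa_set$roas, function(r) {
    seed_px <- pixel_index(r$seed["y"], r$seed["x"], d[2])
    rho <- as.vector(stats::cor(m[, r$pixels, drop = FALSE], m[, seed_px]))
    data.frame(roa_id = r$roa_id, pixel = r$pixels, correlation = rho)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
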
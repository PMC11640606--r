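make_range_map <- function(m, pixel_size_um = 0.8) {
  structure(list(data = m, pixel_size_um = pixel_size_um),
            class = "range_map")
}

test_that("seed finding: flat maps, single bumps, separated bumps, ties", {
  expect_equal(nrow(find_seeds(make_range_map(matrix(0, 20, 20)),
                               noise_floor = 0)), 0L)

  # one smooth bump -> exactly one seed at its peak
  g <- outer(1:31, 1:31, function(y, x) exp(-((y - 16)^2 + (x - 12)^2) / 18))
  s <- find_seeds(make_range_map(g), noise_floor = 0.05, smooth_sigma_px = 0)
  expect_equal(nrow(s), 1L)
  expect_equal(c(s$y, s$x), c(16L, 12L))

  # two bumps separated by more than the neighborhood -> two seeds
  g2 <- outer(1:41, 1:41, function(y, x)
    exp(-((y - 10)^2 + (x - 10)^2) / 8) + exp(-((y - 30)^2 + (x - 32)^2) / 8))
  s2 <- find_seeds(make_range_map(g2), neighborhood_px = 3,
                   noise_floor = 0.05, smooth_sigma_px = 0)
  expect_equal(nrow(s2), 2L)

  # a plateau of equal maxima yields exactly one deterministic seed
  fl <- matrix(0, 15, 15); fl[7:8, 7:8] <- 1
  s3 <- find_seeds(make_range_map(fl), noise_floor = 0.5, smooth_sigma_px = 0)
  expect_equal(nrow(s3), 1L)
  expect_error(find_seeds(make_range_map(fl), neighborhood_px = 0), ">= 1")
})

# Build a dff stack with two synchronous discs on independent noise.
two_disc_dff <- function(T = 120, ny = 40, nx = 40, amp = c(1, 0.8),
                         seed = 5L) {
  set.seed(seed)
  arr <- array(rnorm(T * ny * nx, 0, 0.05), dim = c(T, ny, nx))
  kern1 <- make_temporal_kernel(amp[1], 0.8, 3.2, 0.5)
  kern2 <- make_temporal_kernel(amp[2], 0.8, 3.2, 0.5)
  d <- sqrt(outer((1:ny - 12)^2, (1:nx - 12)^2, `+`))
  fp1 <- which(d <= 4)
  d2 <- sqrt(outer((1:ny - 30)^2, (1:nx - 30)^2, `+`))
  fp2 <- which(d2 <= 3.2)
  m <- matrix(arr, nrow = T)
  i1 <- 20 + seq_along(kern1$trace) - 1
  m[i1[i1 <= T], fp1] <- m[i1[i1 <= T], fp1] + kern1$trace[i1 <= T]
  i2 <- 70 + seq_along(kern2$trace) - 1
  m[i2[i2 <= T], fp2] <- m[i2[i2 <= T], fp2] + kern2$trace[i2 <= T]
  list(dff = dff_from_array(array(m, dim = c(T, ny, nx))),
       fp1 = fp1, fp2 = fp2)
}

test_that("two disjoint synchronous discs grow into two ROAs matching their footprints", {
  fx <- two_disc_dff()
  rp <- range_projection(fx$dff)
  seeds <- find_seeds(rp)
  roas <- grow_roas(fx$dff, seeds, corr_threshold = 0.2, min_roa_area_um2 = 5)
  expect_equal(length(roas$roas), 2L)
  jacc <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  got <- lapply(roas$roas, `[[`, "pixels")
  j1 <- max(jacc(got[[1]], fx$fp1), jacc(got[[2]], fx$fp1))
  j2 <- max(jacc(got[[1]], fx$fp2), jacc(got[[2]], fx$fp2))
  expect_gte(j1, 0.8)
  expect_gte(j2, 0.8)
  # ROAs are pairwise disjoint
  expect_equal(length(intersect(got[[1]], got[[2]])), 0L)
})

test_that("a blob below the minimum ROA area is absent from the output", {
  # 4 um^2 at 0.8 um/px is ~6 px: below the 5 um^2 (7.8 px) floor
  T <- 100
  set.seed(6)
  arr <- array(rnorm(T * 30 * 30, 0, 0.05), dim = c(T, 30, 30))
  kern <- make_temporal_kernel(1.2, 0.8, 3.2, 0.5)
  fp_small <- c(pixel_yx_idx <- c(10 + (10 - 1) * 30, 11 + (10 - 1) * 30,
                                  9 + (10 - 1) * 30, 10 + (9 - 1) * 30,
                                  10 + (11 - 1) * 30, 11 + (11 - 1) * 30))
  m <- matrix(arr, nrow = T)
  idx <- 30 + seq_along(kern$trace) - 1
  m[idx[idx <= T], fp_small] <- m[idx[idx <= T], fp_small] +
    kern$trace[idx <= T]
  dff <- dff_from_array(array(m, dim = c(T, 30, 30)))
  roas <- grow_roas(dff, find_seeds(range_projection(dff)),
                    corr_threshold = 0.2, min_roa_area_um2 = 5)
  # the 6-px blob (3.84 um^2) must have been discarded
  for (r in roas$roas) expect_gte(r$area_um2, 5)
  all_px <- unlist(lapply(roas$roas, `[[`, "pixels"))
  expect_equal(length(intersect(all_px, fp_small)), 0L)
})

test_that("pixels below the correlation threshold are excluded, above included", {
  fx <- two_disc_dff()
  T <- dim(fx$dff$data)[1]
  m <- matrix(fx$dff$data, nrow = T)
  rp <- range_projection(fx$dff)
  seeds <- find_seeds(rp)
  seed_px <- (as.integer(seeds$x[1]) - 1) * 40 + as.integer(seeds$y[1])
  seed_trace <- m[, seed_px]
  # craft two pixels adjacent to the first disc with exact correlations
  set.seed(99)
  low <- trace_with_correlation(seed_trace, rnorm(T), 0.19)
  high <- trace_with_correlation(seed_trace, rnorm(T), 0.30)
  # scale to match typical dff magnitudes and place next to the disc
  yx <- which(matrix(seq_len(40 * 40), 40, 40) %in% fx$fp1, arr.ind = TRUE)
  edge_x <- max((fx$fp1 - 1) %/% 40) + 1
  row_y <- 12
  px_low <- (edge_x + 1 - 1) * 40 + row_y      # one past the disc edge
  px_high <- (edge_x + 1 - 1) * 40 + row_y + 1
  m[, px_low] <- low * 0.2
  m[, px_high] <- high * 0.2
  dff2 <- dff_from_array(array(m, dim = c(T, 40, 40)))
  roas <- grow_roas(dff2, find_seeds(range_projection(dff2)),
                    corr_threshold = 0.2, min_roa_area_um2 = 5)
  px_sets <- lapply(roas$roas, `[[`, "pixels")
  expect_false(any(vapply(px_sets, function(p) px_low %in% p, logical(1))))
  expect_true(any(vapply(px_sets, function(p) px_high %in% p, logical(1))))
  # post-hoc compliance: every member pixel correlates >= threshold
  cc <- roa_seed_correlations(dff2, roas)
  expect_true(all(cc$correlation >= 0.2))
})

test_that("shrinking the minimum area never decreases the number of ROAs", {
  fx <- two_disc_dff(seed = 8L)
  seeds <- find_seeds(range_projection(fx$dff))
  n_prev <- -1L
  for (a in c(40, 20, 10, 5, 2)) {
    n <- length(grow_roas(fx$dff, seeds, 0.2, a)$roas)
    if (n_prev >= 0) expect_gte(n, n_prev)
    n_prev <- n
  }
  expect_error(grow_roas(fx$dff, seeds, corr_threshold = 1.5), "\\[0, 1\\]")
  empty <- grow_roas(fx$dff, seeds[0, ], 0.2, 5)
  expect_equal(length(empty$roas), 0L)
})

test_that("ROA traces average member pixels", {
  dff <- dff_from_array(array(0.3, dim = c(10, 4, 4)))
  expect_equal(extract_roa_trace(dff, list(pixels = c(1, 5, 9))),
               rep(0.3, 10))
  arr <- array(0, dim = c(6, 2, 2))
  a <- c(0, 1, 2, 3, 2, 1); b <- c(1, 1, 0, 2, 2, 0)
  arr[, 1, 1] <- a; arr[, 2, 1] <- b
  expect_equal(extract_roa_trace(dff_from_array(arr), list(pixels = c(1, 2))),
               (a + b) / 2)
  expect_error(extract_roa_trace(dff, list(pixels = 99)), "outside")
})

test_that("event detection closed forms: Gaussian pulse, square pulse, empty traces", {
  dt <- 0.5
  expect_equal(nrow(detect_events(rep(0, 100), dt)), 0L)

  tt <- (0:199) * dt
  gauss <- exp(-(tt - 50)^2 / 2)      # sigma = 1 s, amplitude 1, noiseless
  ev <- detect_events(gauss, dt)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$amplitude_dff, 1, tolerance = 1e-6)
  expect_lt(abs(ev$fwhm_s - 2.3548), dt)
  expect_lt(abs(ev$peak_time_s - 50), dt)

  sq <- rep(0, 60); sq[21:26] <- 1    # 3 s at 2 Hz
  evs <- detect_events(sq, dt)
  expect_equal(nrow(evs), 1L)
  expect_lt(abs(evs$fwhm_s - 3), dt + 1e-9)

  # an event truncated by the recording edge is flagged
  tr <- c(rep(0, 40), seq(0, 1, length.out = 20))
  evt <- detect_events(tr, dt)
  expect_true(evt$truncated[1])
})

test_that("metric summaries satisfy the conservation identities exactly", {
  roas <- list(list(roa_id = 1L, area_um2 = 12), list(roa_id = 2L, area_um2 = 8),
               list(roa_id = 3L, area_um2 = 25))
  events <- data.frame(roa_id = rep(c(1L, 2L, 3L), c(6, 4, 2)),
                       onset_s = 0, peak_time_s = 1,
                       amplitude_dff = 1, fwhm_s = 2, truncated = FALSE)
  ms <- summarize_metrics(roas, events, fov_area_um2 = 100, duration_min = 4)
  expect_equal(ms$signal_density_per_um2_min, 0.03)
  expect_equal(ms$roa_density_per_um2_min, 0.0075)
  expect_identical(ms$signal_density_per_um2_min * 100 * 4, 12)
  expect_identical(ms$roa_density_per_um2_min * 100 * 4, 3)

  one <- summarize_metrics(list(list(roa_id = 1L, area_um2 = 10)),
                           data.frame(roa_id = rep(1L, 10), onset_s = 0,
                                      peak_time_s = 1, amplitude_dff = 1,
                                      fwhm_s = 2, truncated = FALSE),
                           fov_area_um2 = 50, duration_min = 5)
  expect_equal(one$per_roa_frequency_per_min, 2)

  none <- summarize_metrics(list(), events[0, ], 100, 4)
  expect_equal(none$signal_density_per_um2_min, 0)
  expect_true(is.na(none$mean_roa_area_um2))
})
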
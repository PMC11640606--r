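test_that("temporal kernel has the closed-form Gaussian FWHM and flat zero trace", {
  k <- make_temporal_kernel(1, frame_interval_s = 0.1,
                            shape = "gaussian", sigma_s = 1)
  expect_equal(k$fwhm_s, 2 * sqrt(2 * log(2)), tolerance = 1e-10)
  expect_equal(max(k$trace), 1, tolerance = 1e-3)  # discretization only

  k0 <- make_temporal_kernel(0, 0.5, 2, 0.5)
  expect_true(all(k0$trace == 0))
})

test_that("rise-decay kernel FWHM matches a dense-grid half-crossing oracle", {
  cases <- list(c(0.5, 2), c(1, 4), c(0.3, 1.2))
  for (cs in cases) {
    k <- make_temporal_kernel(1, cs[1], cs[2], 0.5)
    # oracle: sample the continuous kernel on a dense grid and locate the
    # half-maximum crossings by linear interpolation
    tg <- seq(1e-6, 60, by = 1e-4)
    f <- (1 - exp(-tg / cs[1])) * exp(-tg / cs[2])
    f <- f / max(f)
    above <- which(f >= 0.5)
    oracle <- tg[max(above)] - tg[min(above)]
    expect_equal(k$fwhm_s, oracle, tolerance = 1e-3)
    # the sampled trace peaks at the amplitude to within discretization
    expect_lt(abs(max(k$trace) - 1), 0.05)
  }
  expect_error(make_temporal_kernel(1, 0.01, 0.01, frame_interval_s = 10),
               "support")
})

test_that("no-event, noise-free movie equals baseline times bleach exactly", {
  cfg <- movie_config(height_px = 16L, width_px = 16L, duration_s = 30,
                      n_events = 0L, noise_sd = 0, motion_artifact_rate = 0,
                      bleach_fraction = 0.2, baseline_level = 100,
                      rng_seed = 1L)
  sim <- make_movie(cfg)
  T <- dim(sim$movie$data)[1]
  tt <- frame_times(sim$movie)
  lambda <- -log(1 - 0.2) / tt[T]
  expected <- 100 * exp(-lambda * tt)
  for (px in c(1, 77, 256)) {
    yx <- cbind((px - 1) %% 16 + 1, (px - 1) %/% 16 + 1)
    expect_equal(sim$movie$data[, yx[1], yx[2]], expected, tolerance = 1e-12)
  }
  expect_equal(nrow(sim$truth), 0L)
})

test_that("identical config and seed give bit-identical movies and truth", {
  a <- make_movie(small_config())
  b <- make_movie(small_config())
  expect_identical(a$movie$data, b$movie$data)
  expect_identical(a$truth, b$truth)
  c <- make_movie(small_config(rng_seed = 43L))
  expect_false(identical(a$movie$data, c$movie$data))
})

test_that("ground truth bookkeeping: n rows, areas within range, events in recording", {
  cfg <- movie_config(height_px = 128L, width_px = 128L, duration_s = 120,
                      n_events = 20L, event_area_um2_range = c(10, 60),
                      rng_seed = 5L)
  sim <- make_movie(cfg)
  tr <- sim$truth
  expect_equal(nrow(tr), 20L)
  # rasterized footprint areas stay within one pixel of the drawn target
  px_area <- cfg$pixel_size_um^2
  expect_true(all(tr$area_um2 >= 10 - px_area & tr$area_um2 <= 60 + px_area))
  expect_true(all(tr$peak_time_s > 0 & tr$peak_time_s < 120))
  expect_true(all(tr$amplitude_dff > 0))
  expect_true(all(tr$fwhm_s > 0))
  fps <- attr(tr, "footprints")
  expect_true(all(lengths(fps) > 0))
  # conservation: the injected dF/F0 integrates to amplitude * kernel area
  clean_cfg <- movie_config(height_px = 64L, width_px = 64L, duration_s = 60,
                            n_events = 1L, noise_sd = 0,
                            motion_artifact_rate = 0, bleach_fraction = 0,
                            rng_seed = 9L)
  simc <- make_movie(clean_cfg)
  fp <- attr(simc$truth, "footprints")[[1]]
  m <- matrix(simc$movie$data, nrow = dim(simc$movie$data)[1])
  dff <- m[, fp[1]] / clean_cfg$baseline_level - 1
  kern <- make_temporal_kernel(simc$truth$amplitude_dff[1],
                               clean_cfg$event_rise_s, clean_cfg$event_decay_s,
                               clean_cfg$frame_interval_s)
  expect_equal(sum(dff), sum(kern$trace), tolerance = 0.02 * sum(kern$trace))
})

test_that("noise clamping is recorded and intensities stay non-negative", {
  cfg <- movie_config(height_px = 16L, width_px = 16L, duration_s = 30,
                      baseline_level = 5, noise_sd = 10, n_events = 0L,
                      motion_artifact_rate = 0, rng_seed = 2L)
  sim <- make_movie(cfg)
  expect_true(all(sim$movie$data >= 0))
  expect_gt(attr(sim$movie$data, "n_clamped"), 0)
})

test_that("invalid movie configs are rejected", {
  expect_error(movie_config(bleach_fraction = 1), "bleach")
  expect_error(movie_config(duration_s = 2), "10 frames")
  expect_error(movie_config(height_px = 32L, width_px = 32L,
                            event_area_um2_range = c(100, 900)), "fit")
  expect_error(movie_config(event_amplitude_dff_range = c(-1, 1)), "positive")
})

test_that("census table respects rates and count hierarchy", {
  # all marker rates zero: marker counts all zero
  t0 <- make_census_table(c(g = 5L),
                          list(pdgfra = 0, myrf = 0, ki67 = 0), rng_seed = 1L)
  expect_true(all(t0$pdgfra_gfp == 0 & t0$myrf_gfp == 0 & t0$ki67_gfp == 0))
  # rate 1 for PDGFRa: every GFP+ cell is PDGFRa+
  t1 <- make_census_table(c(g = 10L),
                          list(pdgfra = 1, myrf = 0, ki67 = 0.2), rng_seed = 2L)
  expect_identical(t1$pdgfra_gfp, t1$gfp_pos)
  # invariant: marker-positive recombined cells never exceed GFP+ totals
  tb <- make_census_table(c(a = 50L, b = 50L),
                          list(pdgfra = 0.5, myrf = 0.3, ki67 = 0.1),
                          rng_seed = 3L)
  expect_true(all(tb$pdgfra_gfp + tb$myrf_gfp <= tb$gfp_pos))
  expect_error(make_census_table(c(g = 3L),
                                 list(pdgfra = 1.2, myrf = 0, ki67 = 0)),
               "\\[0, 1\\]")
})

test_that("seeded binomial marker rates recover the nominal fraction", {
  # 200 FOVs at rate 0.75: the mean fraction lies within the binomial CI
  tb <- make_census_table(c(g = 200L),
                          list(pdgfra = 0.75, myrf = 0, ki67 = 0),
                          rng_seed = 7L, mean_gfp = 100)
  frac <- tb$pdgfra_gfp / tb$gfp_pos
  se <- sqrt(0.75 * 0.25 / sum(tb$gfp_pos))
  expect_lt(abs(mean(frac) - 0.75), 4 * se + 0.005)
})

test_that("axon images encode the analytic area ratio", {
  img <- make_axon_image(15, 10, image_size = 64)
  expect_equal(img$true_ratio, 2.25)
  # rasterized pixel counts agree with the analytic ratio within 2%
  raster_ratio <- (sum(img$mbp > 0) + sum(img$nf > 0)) / sum(img$nf > 0)
  expect_lt(abs(raster_ratio - img$true_ratio) / img$true_ratio, 0.02)
  # ratio tends to 1 from above as the ring thins
  thin <- make_axon_image(10.5, 10, image_size = 64)
  expect_gt(thin$true_ratio, 1)
  expect_lt(thin$true_ratio, 1.11)
  expect_error(make_axon_image(10, 15), "smaller")
  expect_error(make_axon_image(40, 10, image_size = 64), "exceed")
})

test_that("movies round-trip through TIFF plus JSON sidecar", {
  sim <- make_movie(small_config(n_events = 1L))
  path <- file.path(tempdir(), "roundtrip.tif")
  write_movie_tiff(sim$movie, path, config_echo = list(seed = 42))
  back <- read_movie_tiff(path)
  expect_equal(back$pixel_size_um, sim$movie$pixel_size_um)
  expect_equal(back$frame_interval_s, sim$movie$frame_interval_s)
  # 16-bit quantization: relative error bounded by 1/65535 of full scale
  expect_lt(max(abs(back$data - sim$movie$data)),
            max(sim$movie$data) / 65535 * 1.01)
  expect_error(read_movie_tiff(file.path(tempdir(), "nosidecar.tif")),
               "sidecar")
  unlink(c(path, paste0(path, ".json")))
})
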
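#!/usr/bin/env Rscript
# Simulate the study conditions: three 5-minute recordings per condition
# (control-like vs cuprizone-like Ca2+ activity), written as TIFF stacks
# with JSON calibration sidecars and ground-truth CSVs, plus the census
# table and a batch of myelinated-axon images used by 03_quantify.R.
#
# Movies are kept at the acquisition geometry (256 x 256 px, 2 Hz) so the
# downstream detection runs under realistic conditions; with three
# recordings per condition the whole step stays desk-scale.

library(roaevents)

out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

n_per_group <- 3L
# inter-animal variability: event counts jittered ~15% around the preset
n_events_by_rec <- list(control = c(34L, 40L, 46L),
                        cuprizone = c(70L, 80L, 92L))
for (preset in c("control", "cuprizone")) {
  for (i in seq_len(n_per_group)) {
    cfg <- preset_movie_config(preset, rng_seed = 1000L * i +
                                 ifelse(preset == "control", 0L, 500L),
                               n_events = n_events_by_rec[[preset]][i])
    sim <- make_movie(cfg)
    stem <- file.path(out, sprintf("%s_%02d", preset, i))
    write_movie_tiff(sim$movie, paste0(stem, ".tif"),
                     config_echo = unclass(cfg))
    truth <- sim$truth
    write.csv(truth, paste0(stem, "_truth.csv"), row.names = FALSE)
    message(sprintf("%s: %d events over %d sites, mean area %.1f um^2",
                    basename(stem), nrow(truth),
                    length(unique(truth$site_id)), mean(truth$area_um2)))
    rm(sim); invisible(gc(verbose = FALSE))
  }
}

# census fixture: recombined-lineage marker rates per condition
census <- make_census_table(
  c(ctrl = 12L, cKD = 12L),
  list(ctrl = list(pdgfra = 0.76, myrf = 0.12, ki67 = 0.05),
       cKD = list(pdgfra = 0.88, myrf = 0.06, ki67 = 0.05)),
  rng_seed = 7L
)
write.csv(census, file.path(out, "census.csv"), row.names = FALSE)

# myelinated axons: 40 per condition with lognormal radii; the cKD-like
# group gets slightly thicker rings (higher true area ratio)
set.seed(11)
axons <- do.call(rbind, lapply(c("ctrl", "cKD"), function(g) {
  n <- 40L
  r_in <- pmin(pmax(rlnorm(n, log(8), 0.2), 5), 13)
  k <- if (g == "ctrl") 1.45 else 1.52
  data.frame(group = g, axon_id = seq_len(n), r_in = r_in,
             r_out = r_in * runif(n, k - 0.1, k + 0.1))
}))
write.csv(axons, file.path(out, "axon_geometry.csv"), row.names = FALSE)

message("simulation inputs written to ", out)
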
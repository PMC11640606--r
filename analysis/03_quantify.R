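#!/usr/bin/env Rscript
# Census and myelin quantification on the simulated fixtures: recombined
# cell densities (mm^-3), lineage fractions and differentiation ratios per
# FOV, and per-axon relative MBP areas measured from rasterized two-channel
# axon images against their analytic ground truth.

library(roaevents)

sim_dir <- "results/sim"
out <- "results/quantify"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

## ---- census: densities and lineage fractions ------------------------------
census <- read.csv(file.path(sim_dir, "census.csv"))
census$opc_density_mm3 <- cell_density(census$pdgfra_gfp,
                                       census$fov_area_um2[1],
                                       census$thickness_um[1])
census$ol_density_mm3 <- cell_density(census$myrf_gfp,
                                      census$fov_area_um2[1],
                                      census$thickness_um[1])
census <- lineage_fractions(census)
write.csv(census, file.path(out, "census_quantified.csv"), row.names = FALSE)

agg <- aggregate(cbind(opc_density_mm3, frac_pdgfra, differentiation_ratio)
                 ~ group, census, mean)
message("per-group census means:")
print(agg)

## ---- myelin: per-axon relative MBP area -----------------------------------
axons <- read.csv(file.path(sim_dir, "axon_geometry.csv"))
meas <- do.call(rbind, lapply(seq_len(nrow(axons)), function(i) {
  img <- make_axon_image(axons$r_out[i], axons$r_in[i], image_size = 72)
  r <- per_axon_relative_mbp_area(img$mbp, img$nf, pixel_size_um = 0.1)
  r$group <- axons$group[i]
  r$axon_id <- axons$axon_id[i]
  r$true_ratio <- img$true_ratio
  r
}))
write.csv(meas, file.path(out, "axon_measurements.csv"), row.names = FALSE)

ok <- meas$measurable
message(sprintf("measured %d/%d axons; median |ratio error| %.2f%%",
                sum(ok), nrow(meas),
                100 * median(abs(meas$relative_mbp_area[ok] -
                                   meas$true_ratio[ok]) /
                               meas$true_ratio[ok])))
for (g in unique(meas$group)) {
  message(sprintf("  %s: mean relative MBP area %.3f", g,
                  mean(meas$relative_mbp_area[ok & meas$group == g])))
}
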
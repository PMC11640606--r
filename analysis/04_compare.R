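#!/usr/bin/env Rscript
# Statistical comparison layer over the detected metrics and quantified
# fixtures: normality-gated two-group tests per Ca2+ metric, fold changes of
# the cuprizone-like condition against the control-like reference tested
# against unity, a two-way ANOVA on the census differentiation ratio, and a
# Gaussian-fit comparison of the per-axon relative MBP area distributions.

library(roaevents)

out <- "results/compare"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

## ---- Ca2+ metrics: control-like vs cuprizone-like --------------------------
metrics <- read.csv("results/detect/metrics_all.csv")
tests <- run_compare(metrics)
write.csv(tests, file.path(out, "ca_metric_tests.csv"), row.names = FALSE)
message("Ca2+ metric comparisons:")
print(tests[, c("comparison", "test", "statistic", "p_value", "branch")])

## fold change of signal density vs the control-like reference mean
ref_mean <- mean(metrics$signal_density_per_um2_min[metrics$group == "control"])
fc <- fold_change(
  metrics$signal_density_per_um2_min[metrics$group == "cuprizone"], ref_mean)
fc_test <- one_sample_vs_unity(fc)
write.csv(cbind(fc_test, mean_fc = mean(fc)),
          file.path(out, "signal_density_fold_change.csv"), row.names = FALSE)
message(sprintf("signal-density fold change %.2f vs unity: t = %.2f, p = %.3g",
                mean(fc), fc_test$statistic, fc_test$p_value))

## ---- census: two-way layout (group x region) on lineage fractions ----------
census <- read.csv("results/quantify/census_quantified.csv")
# the simulated census has one region; synthesize the second factor from
# odd/even FOVs purely to exercise the two-factor interface
census$region2 <- ifelse(census$fov %% 2 == 0, "dorsal", "ventral")
aov_res <- two_way_anova_mc(census$frac_pdgfra, census$group, census$region2)
write.csv(aov_res$anova_table, file.path(out, "census_anova.csv"),
          row.names = FALSE)
write.csv(aov_res$pairwise, file.path(out, "census_pairwise.csv"),
          row.names = FALSE)
message("census two-way ANOVA (OPC fraction):")
print(aov_res$anova_table)

## ---- myelin: Gaussian fits of the relative-MBP-area distributions ----------
meas <- read.csv("results/quantify/axon_measurements.csv")
meas <- meas[meas$measurable, ]
brks <- seq(min(meas$relative_mbp_area) - 0.05,
            max(meas$relative_mbp_area) + 0.05, length.out = 18)
hist_of <- function(g) {
  h <- hist(meas$relative_mbp_area[meas$group == g], breaks = brks,
            plot = FALSE)
  data.frame(mid = h$mids, count = h$counts)
}
fit_cmp <- gaussian_fit_compare(hist_of("ctrl"), hist_of("cKD"))
print(fit_cmp)
write.csv(data.frame(rss_shared = fit_cmp$rss_shared,
                     rss_separate = fit_cmp$rss_separate,
                     f_statistic = fit_cmp$f_statistic,
                     df_extra = fit_cmp$df_extra,
                     df_separate = fit_cmp$df_separate,
                     p_value = fit_cmp$p_value),
          file.path(out, "mbp_area_gaussian_fit.csv"), row.names = FALSE)
message("comparison outputs written to ", out)
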
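Package: roaevents
Title: Region-of-Activity Calcium Event Detection for Two-Photon Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detection and quantification of localized Ca2+ transients in
    time-lapse two-photon fluorescence movies of GCaMP-expressing glia.
    Per-pixel basal fluorescence is estimated by robust least-squares
    polynomial fitting along time, movies are normalized to dF/F0, and
    regions of activity (ROAs) are segmented by seeded, correlation-based
    region growing on the temporal range projection. Per-ROA events are
    extracted with amplitude and full-width-at-half-maximum duration, and
    summarized as signal/ROA densities and per-ROA frequencies. The package
    also provides a synthetic movie generator with ground truth, census and
    myelin quantification helpers (cell densities, lineage fractions,
    per-axon relative myelin area), and the accompanying statistical
    comparison layer (normality-gated two-group tests, one-sample tests of
    fold change against unity, two-way ANOVA with multiple comparisons, and
    Gaussian histogram fits compared by the extra-sum-of-squares F test).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    EBImage,
    minpack.lm,
    emmeans
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
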
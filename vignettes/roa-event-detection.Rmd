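---
title: "Region-of-activity Ca2+ event detection: model, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-of-activity Ca2+ event detection: model, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roaevents)
```

## The problem

In vivo two-photon recordings of GCaMP-expressing glia show spontaneous,
spatially localized Ca2+ transients riding on a slowly decaying
(photobleaching) baseline with shot-like noise and occasional single-frame
motion artifacts. The scientific quantities of interest are per-recording:
how many transients occur (signal density, events per um^2 of field per
minute), where they occur (regions of activity, ROAs, and their areas), how
often each ROA fires (per-ROA frequency), and how large and long individual
transients are (amplitude in dF/F0, duration as full width at half maximum).
This package implements the whole chain — preprocessing, per-pixel baseline
(F0) estimation, dF/F0 normalization, ROA segmentation, event extraction,
summary metrics — plus the census/myelin quantification arithmetic and the
statistical comparison layer used around such recordings, and a synthetic
movie generator with exact ground truth so that every stage is verifiable
without access to in vivo data.

## The detection model, stage by stage

**Preprocessing.** A temporal median filter (default window 3 frames, the
smallest that removes a single displaced frame while retaining sharp
transient edges) suppresses whole-frame motion artifacts. Denoising then
applies the Anscombe variance-stabilizing transform `2*sqrt(x + 3/8)`,
separable Gaussian smoothing, and the algebraic inverse. The default
smoothing is temporal only (`sigma_t = 0.75` frames, `sigma_s = 0`):
spatial smoothing bleeds event signal into a correlated one-pixel halo
around each active domain, which inflates grown ROA areas and dilutes
ROA-mean amplitudes, while temporal smoothing plus the median filter
already reduce the per-pixel noise sd by about a factor of two. Both sigmas
and the stage order are configuration knobs.

**Baseline (F0).** Each pixel's time course is fitted with a least-squares
polynomial of user-selectable degree (default 3) on a centered and scaled
time axis for numerical conditioning. Degree 3 tracks a 5-minute
exponential bleach to about 1-2% without absorbing transients; the
generator deliberately bleaches with an exponential — not a polynomial — so
this model mismatch is exercised by the tests. Because Ca2+ transients are
strictly positive deviations, a plain least-squares fit is biased upward
inside events. The robust refit (default 2 iterations) therefore estimates
each pixel's noise scale from its *negative* residuals only (the lower
residual half is event-free for symmetric noise) and excludes frames whose
positive residual exceeds `robust_k = 2` noise sds. The exclusion refit is
solved by an imputation fixed point — masked frames are replaced by the
current fit and the full design refitted until the coefficients converge —
which is exactly the masked least-squares solution at convergence and stays
fully vectorized over all pixels. With zero robust iterations the result is
the closed-form normal-equations solution (a tested oracle equivalence).

**dF/F0 and the range projection.** The stack is normalized as
`(F - F0)/F0`; pixels whose fitted F0 is non-positive at any frame (e.g.
all-zero traces) are masked with a message, never silently zeroed. The
seeding map is the per-pixel temporal range (max - min) of dF/F0.

**Seeding.** Seeds are strict local maxima of the range projection within a
Chebyshev neighborhood (default radius 2 px) above a noise floor, with a
deterministic row-major tie-break on plateaus. Two choices here were
genuinely open:

* *Noise floor.* The default is `median + 3 * MAD` of the range map. The
  range of T noise draws concentrates around ~6.5 noise sds with small
  dispersion, so a floor must sit above the noise *median*; the MAD serves
  as the robust dispersion about it. Active pixels are rare enough not to
  move either statistic appreciably.
* *Smoothing before seeding.* The raw range values over a spatially
  extended active domain are a plateau plus noise, so raw local maxima
  would fragment one microdomain into many seeds. The map is therefore
  lightly smoothed (Gaussian, default 1.5 px) before maxima are picked;
  region growing itself always uses the raw traces.

**Region growing.** All seeds grow simultaneously in lockstep rounds over
8-connected frontiers. A candidate pixel joins the adjacent region whose
*seed pixel trace* it correlates with most (Pearson, all frames), provided
that correlation reaches the threshold (default 0.2). Anchoring on the seed
trace rather than the evolving region mean makes the criterion a fixed,
post-hoc checkable bound for every member pixel. Competing claims resolve
by larger correlation, then higher seed range value, then seed order, so
growth is deterministic. After growth, an adjacent region is absorbed into
a higher-priority neighbor only when *every* one of its pixels also meets
the correlation bound against the retained seed — fragments of one
microdomain merge, distinct domains do not, and the per-pixel bound against
the single reported seed is preserved exactly. Regions smaller than the
minimum ROA area (default 5 um^2) are discarded last.

**Events.** Each ROA's mean dF/F0 trace is scanned for maximal excursions
above `baseline + k * sigma_noise` (default `k = 3`), with the baseline
level and noise sd iteratively re-estimated from subthreshold samples so
events do not inflate them. Amplitude is the trace value at the excursion
maximum; duration is the full width at half that maximum with linear
interpolation at the crossings, and edge-truncated events are flagged.
Because an ROA trace averages tens to hundreds of pixels, `3 * sigma` of
the trace noise can fall below 2% dF/F0, where a pure k-sigma rule reports
physiologically meaningless wiggles; excursions below `min_amplitude_dff`
(default 0.1, i.e. 10% dF/F0, about the resolvability floor of a slow
genetically encoded indicator in vivo) are therefore discarded. Both knobs
are configuration parameters.

**Metrics.** Signal density = events / (FOV area x duration); ROA density
likewise for ROAs; per-ROA frequency is the mean over ROAs of events per
minute; plus means of ROA area, amplitude, and FWHM. The density identities
(`density x area x duration = count`) hold exactly by construction and are
asserted in the tests.

## The synthetic generator

`make_movie()` composes `F0(t) * (1 + sum of events) + noise`:

* 256 x 256 px fields, 0.8 um/px (a 5 um^2 minimum ROA is then ~8 px,
  consistent with a 20x objective over such a field), 2 Hz for 5 minutes —
  frame rate and pixel size are explicit configuration, not claims about
  any particular instrument.
* Baseline 100 a.u. with a single-exponential 20% bleach.
* Events are filled ellipses with mild eccentricity jitter; the temporal
  kernel is a product of rising and decaying exponentials whose FWHM is
  computed on the continuous kernel by root finding, so every injected
  event carries an exact analytic duration. Default time constants
  (rise 0.8 s, decay 3.2 s, FWHM 3.9 s) sit between the two condition
  presets: the control-like preset (rise 1 / decay 4 s, FWHM 4.9 s; 40
  events in 20 large domains of 60-110 um^2) and the cuprizone-like preset
  (rise 0.55 / decay 2.75 s, FWHM 3.2 s; 80 events in 40 small domains of
  15-55 um^2), reproducing the demyelination signature of more, smaller,
  briefer transients.
* Gaussian noise sd 8 a.u. by default, so the weakest default event
  (0.5 dF/F0 on baseline 100) has peak SNR >= 5; a Poisson-Gaussian model
  is available. Negative intensities are clamped at zero and counted.
* Motion artifacts are single whole-frame translations of 1-3 px (Poisson
  count, default expectation 2 per recording) — exactly the disturbance the
  temporal median filter exists to remove.

What the generator does *not* emulate: cell morphology and process
arborization, vasculature shadows, focal drift, anesthesia-state
transitions, or spatially overlapping/propagating events. Passing the
recovery benchmarks therefore demonstrates correctness of the algorithmic
chain under controlled conditions, not field performance on arbitrary in
vivo data.

## Census, myelin, and statistics

Census tables hold per-FOV marker co-expression counts; densities divide by
FOV area times counting depth (the imaged stack depth when known, else the
section thickness — both are recorded, since either convention appears in
practice). Lineage fractions and the differentiation ratio
(mature oligodendrocytes per recombined OPC) guard zero denominators with
`NA` plus a warning. The per-axon relative myelin area reads the "area
delimited by the myelin ring" as the full filled area inside the outer MBP
boundary (axon included), which yields ratios >= 1 and matches reported
means of ~2.2-2.4 for myelinated axons; an annulus-only variant sits behind
a flag. MBP thresholds default to Otsu's rule on the analysis region and
are always echoed in the output.

The statistics layer mirrors mainstream biostatistics practice: a
Shapiro-Wilk gate (all groups p >= 0.05) routes to the classic unpaired t
test or the Wilcoxon rank-sum; fold changes against an untreated reference
mean are tested with a one-sample t against 1; factorial census designs use
a two-way ANOVA with Sidak-corrected pairwise cell comparisons (the
correction is selectable — no specific procedure is canonical here, and no
headline result depends on the choice); histogram pairs are compared by
unweighted least-squares Gaussian fits and the extra-sum-of-squares F test,
with moment-based starting values and no silent fallback on
non-convergence. Replicates are collapsed to one value per animal before
testing by default; FOV-level testing is available behind an explicit flag.

## Numerical choices and degenerate inputs

* Polynomial bases are evaluated on a centered/scaled time axis; degree is
  capped by `degree + 1 <= T`.
* Zero-variance traces cannot correlate and never join an ROA; all-zero
  pixels are masked at the F0 stage.
* Flat traces yield no events; noiseless traces fall back to an epsilon
  threshold so closed-form pulse tests are exact.
* Ties in seeding and growth are broken deterministically (range value,
  then row-major order); re-running any stage on identical input is
  bit-identical.
* The 16-bit TIFF writer stores the intensity scale in the JSON sidecar, so
  round trips lose only 16-bit quantization.

## Problem sizes used in the shipped analyses

The validation suite runs one full-geometry benchmark (256 x 256 px, 2 Hz,
5 min, 50 events at SNR >= 5) plus one recording per condition preset; the
numbered analysis scripts under `analysis/` use three recordings per
condition, 24 census FOVs, and 80 synthetic axons. These sizes give stable
recovery statistics (event counts of 40-120 per recording) while keeping a
complete re-run at desk scale.

## Known limitations

* ROAs are static: events at the same location share one region, and
  propagating activity is not split into subevents or tracked over time.
* Amplitude is read from the ROA-mean trace after preprocessing, so very
  sharp transients undersampled at 2 Hz lose a few percent of peak height
  to the median filter and temporal smoothing (the recovery benchmark
  bounds the combined bias at ~6% median).
* The Anscombe-based denoiser is a generic variance-stabilized smoother
  behind a pluggable interface, not a reimplementation of any published
  denoising algorithm.
* Censuses are count tables: no cell segmentation is performed, matching
  the assisted-counting workflow the quantification layer serves.
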
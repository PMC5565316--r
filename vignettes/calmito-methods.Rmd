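---
title: "Methods: calcium transients, mitochondrial morphometry, and paired cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calcium transients, mitochondrial morphometry, and paired cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

calmito analyses live-imaging recordings of enteric (submucous-plexus)
neurons of the kind collected from gut biopsies: single-channel calcium
time-lapse movies in which ganglion neurons respond to a depolarising
stimulus, and 3D(+time) stacks of the potentiometric dye TMRE, which
accumulates in mitochondria in proportion to their membrane potential.
Because such patient recordings are not generally shareable, the package
carries seeded simulators that generate both modalities with known ground
truth; every stage of the analysis is validated against those simulations.

## Calcium analysis

**Model.** A recording is a T×Y×X intensity array with a stimulus protocol
(label, start, end in seconds; windows are half-open `[start, end)`).
Perfusion drift is removed by translation-only registration of every frame
to the first frame, using phase cross-correlation with subpixel refinement
(local upsampled-DFT evaluation, 10× by default). Each neuron's trace is
the per-frame mean over its ROI; traces are expressed as F/F0 with F0 the
mean fluorescence over a pre-stimulus baseline window, so baseline sits at
1 and an a% transient peaks at 1 + a/100.

**Transient rule.** A neuron is a responder when its peak ratio in the
evaluation window (stimulus window plus a 10 s tail, because transients
outlast a 10 s stimulus) strictly exceeds `1 + 5 × noise_sigma`. The
intrinsic noise level `noise_sigma` is the standard deviation of the
baseline ratio after removing a linear trend — detrending keeps a slow
bleach ramp from inflating the estimate; a robust alternative
(1.4826 × MAD) is selectable. The strict inequality means a peak landing
exactly on the threshold is not a response ("exceeded" is read strictly).
The maximum amplitude is `(peak − 1) × 100`, the percentage change above
baseline, with the argmax taken at the first frame on ties.

**Summaries.** Per stimulus, the package reports the percentage of
responders and the mean maximum amplitude. The amplitude mean is taken
over *all* analysed neurons by default (`amplitude_over = "all"`), with a
switch for responders-only, since published summaries pair amplitude with
responder counts without stating the denominator. For cohort statistics,
neurons are first averaged within subject, so each subject contributes one
value per metric.

**Defaults.** Baseline window: all frames before the first stimulus
(minimum 10 frames for a noise estimate). Threshold multiplier: 5.
Evaluation tail: 10 s. Registration upsampling: 10×, with a warning (never
an error) when any shift exceeds 20% of the image width. Coordinates are
0-based `(t, y, x)`.

## Mitochondrial (TMRE) analysis

**Corrections.** The background is a single scalar — the 5th percentile of
in-mask intensities — subtracted and clipped at zero. For time series,
photobleaching is corrected by rescaling each frame's global mean to frame
1's (the first frame is assumed brightest); raw factors pass through an
isotonic non-decreasing fit and are floored at 1, so genuine monotone
bleach is undone without chasing frame-to-frame fluctuation of the global
mean. Deconvolution is deliberately not replicated: detection operates on
(and is validated against) PSF-blurred synthetic truth instead.

**Morphometry.** All geometry is in µm/µm³ on anisotropic voxels. Within
the ganglion mask: total mitochondrial volume by absolute-intensity
thresholding (default threshold: half the mask's 99.5th-percentile
intensity, configurable because absolute instrument thresholds are not
transferable); `volume_ratio` = mitochondrial / mask volume; spots as
26-neighbourhood local maxima of a scale-normalised Laplacian-of-Gaussian
(default scale 0.46 µm ≈ expected radius 0.8 µm / √3), greedily separated
by ≥ 1.5 µm; density as spots per 1000 µm³; and single-mitochondrion
volumes as 26-connected components of the thresholded volume, with
components holding more than one spot split by seeded descending-intensity
region growing (a marker-based watershed).

**Fluctuation.** The brightest spots (default 500, sorted by
centre intensity with `(z, y, x)` lexicographic tie-break) are tracked by
nearest-neighbour linking within 1 µm/frame (tracks are dropped when
lost; no merge/split handling). Intensity is sampled in a fixed 0.5 µm
sphere; variation is expressed in percent of each spot's own temporal mean
and summarised as the temporal standard deviation of that series (100 ×
coefficient of variation). CV% is this package's declared convention —
the field plots "intensity variations (%)" without defining the summary
statistic. The subject-level value is the mean score over tracked spots.

## Paired cohort statistics

Subjects arrive in patient/control pairs (couples sharing diet and
lifestyle), so group differences are tested within pairs. For each metric,
both groups pass a Shapiro–Wilk gate (α = 0.05; degenerate all-equal
samples are routed nonparametric): normal → paired t-test, otherwise the
Wilcoxon signed-rank test on within-pair differences ("Wilcoxon T-test"
is interpreted as the signed-rank test, since the design is paired). Zero
differences are dropped (Wilcoxon's convention) and n is reported after
dropping. For n ≤ 15 the two-sided p-value is exact — the positive-rank
sum distribution is built by generating-function convolution over doubled
average ranks, which handles ties, and the two-sided value is
`min(1, 2·min(P(W ≤ w), P(W ≥ w)))`; above that, a normal approximation
with the usual tie correction (no continuity correction). The 2×2
chi-squared (e.g. a gender table) is Pearson's without Yates continuity
correction — with correction the printed p of such small tables is not
reproducible. Correlations of imaging metrics with clinical covariates
(age, SCOPA GI, UPDRS-III off, disease duration) use Spearman's rho
(Pearson on average ranks) with a two-sided t approximation; Spearman is
preferred over linear correlation as the named nonparametric choice.
Bonferroni correction is applied within each comparison family: the
metric family for paired tests, the four covariates for each metric's
correlations; family sizes are recorded in the output.

## What the simulators emulate — and what they do not

**Calcium movies.** Ganglia of hard-edged disc somata (radius 4 px) at
baseline 1000 ADU over 100 ADU background; responders rise instantaneously
at stimulus onset to `baseline × (1 + a/100)` and decay single-
exponentially (τ = 5 s — the published traces show only a sharp rise, so
the shape is a free choice); additive Gaussian pixel noise (SD 30 ADU,
i.e. ≈ 0.004 ratio units at the trace level for a ~50-pixel ROI), optional
Poisson resampling (off by default), optional global rigid drift, 16-bit
quantisation at 2 Hz. Acquisition rate and bit depth are configurable
defaults, not claims. The responder fraction is applied exactly
(`round(fraction × n)` neurons), so recovery error measures the detector,
not binomial sampling. Amplitudes are Gaussian (mean 8%, SD 2%) truncated
at 4% — at least twice the 5σ threshold implied by the default noise.

**TMRE stacks.** Ellipsoidal mitochondria (semi-axes ~0.8 ± 0.15 µm,
truncated at 0.3 µm) placed uniformly inside a ganglion ellipsoid with a
minimum separation (3.5 µm by default), rasterised on (0.5, 0.25, 0.25) µm
voxels; per-mitochondrion intensity follows a mean-reverting
(Ornstein–Uhlenbeck) process around its base level with a configurable
temporal CV (10%) and correlation time (10 s), independent across
mitochondria — the published observation is only that intensity
"fluctuates substantially", so the process is a modelling choice;
Gaussian PSF blur (σ = 0.4, 0.15, 0.15 µm, spinning-disk scale), constant
background (100 ADU), multiplicative bleach (1%/frame, first frame
brightest), 16-bit quantisation. The default frame interval is 30 s,
i.e. a ~900 s fluctuation recording sampled as ~30 volumes; with the 10 s
correlation time this makes successive samples nearly independent, so the
temporal-SD fluctuation score is an essentially unbiased estimate of the
simulated CV. (At much shorter intervals the autocorrelation of short
series biases a temporal SD low — that is a property of the statistic,
not of the pipeline.)

**Not emulated:** optical sectioning artifacts, dye diffusion, tissue
autofluorescence texture, mitochondrial motility or fission/fusion, and
deconvolution. Passing recovery tests therefore demonstrates correctness
of the measurement chain under the stated image-formation model, not
robustness to every property of real tissue. One known simulator-specific
artifact: hard-edged discs make post-registration subpixel resampling
inject frac-shift-dependent edge flicker into traces, inflating the
estimated noise level (the 5σ rule then legitimately demotes responders).
Real somata have soft optical edges and do not show this to the same
degree; drifted-movie validation is therefore done at the shift level,
and trace-level recovery is run on drift-free movies.

**Cohorts for statistical calibration.** Testing size and power of the
paired design needs hundreds of replicate cohorts, which is not feasible
through full image simulation; `simulate_cohort()` instead draws
subject-level summaries directly as pair effect + subject residual. For
the responder percentage: control mean 57.3%, pair-effect SD 22, residual
SD 15 (total between-subject SD ≈ 27, intraclass correlation ≈ 0.68),
clamped to [0, 100] — variability at the scale reported for such cohorts,
with the within-couple correlation that motivates paired recruitment.
These values were fixed analytically (a 20-point shift then has expected
paired power ≈ 0.9 at n = 15) before any calibration test was run.

## Numerical choices and degenerate inputs

- FFT-based Gaussian blur uses a periodised, normalised kernel (sums are
  conserved); phase correlation applies a Hann window.
- Local-maxima plateaus are broken deterministically (lowest linear
  index); spot ordering and top-N selection have full lexicographic
  tie-breaks, so outputs are reproducible.
- All randomness flows through one seeded generator per simulation;
  `.Random.seed` is saved and restored, so simulations neither perturb nor
  depend on the caller's RNG state. Identical parameters + seed give
  bit-identical arrays.
- Degenerate inputs error early with messages: empty ROI after clipping,
  F0 ≤ 0, baseline shorter than 10 frames, empty masks, zero-margin 2×2
  tables, all-zero paired differences (reported as NA/not-significant at
  the cohort level), background not below the maximum intensity.
- Problem sizes used in validation were chosen for desk-scale runs:
  300 neurons on a 320×320 field for calcium recovery, 300 mitochondria
  in a 12×48×200×200 stack for morphometry, 200 replicate cohorts of 15
  pairs for calibration, and a 5-pair end-to-end fixture for determinism.

## Known limitations

- Registration is translation-only; rotation or non-rigid tissue motion
  is out of scope (as is automatic neuron segmentation — ROIs are inputs).
- Spot tracking is greedy nearest-neighbour with a gate; no merge/split.
- The absolute-intensity threshold default (half the 99.5th percentile)
  is a heuristic standing in for unreported instrument settings; studies
  should fix it explicitly via configuration when comparing groups.
- TMRE intensity is not converted to millivolts, and no deconvolution is
  performed.
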
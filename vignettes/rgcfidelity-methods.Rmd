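---
title: "Models and methods in rgcfidelity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in rgcfidelity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgcfidelity)
```

This vignette is the package's own account of the models and estimators it
implements, the parameters that matter, the numerical choices made where
several conventions were defensible, and what the built-in synthetic-data
generators do and do not emulate.

## The response model

All physiology analyses assume the standard reverse-correlation picture of
a retinal ganglion cell (RGC): a linear spatiotemporal receptive field
followed by a static nonlinearity and stochastic spiking (the LNP cascade).
The simulator builds cells with exactly this structure, so every estimator
can be checked against known parameters.

**Stimulus.** `generate_checkerboard()` draws each checker on each frame
independently and equiprobably from {-1, +1} (zero-mean contrast coding).
Zero-mean coding makes the spike-triggered average an unbiased estimate of
the linear filter; whiteness in space and time is what justifies reading
the STA as the receptive field.  The two stock geometries are 150-µm
squares at 66-ms refresh (rod-dominated light levels) and 75-µm squares at
33-ms refresh (cone-dominated); the light level itself is carried only as
metadata — it is the simulated cell, not the stimulus, that changes regime.
Frames per clip use `floor(duration / refresh)`; a partial trailing frame
is dropped.  Checker (1,1) spans [0, square) × [0, square) µm from the
top-left corner and all receptive-field geometry is reported in µm.

**Linear stage.** The simulator's filter is rank-one by construction: an
elliptical Gaussian spatial profile (defaults σ = 55 × 40 µm) times a
biphasic temporal kernel, the difference of two gamma-shaped cascades with
common shape `p`:

    k(t) = (t/τ_f)^p e^(-t/τ_f) − w (t/τ_s)^p e^(-t/τ_s).

With τ_s > τ_f and 0 < w < 1 the kernel has one early lobe, one delayed
opposite-sign lobe, and a unique zero crossing with closed form
`t0 = (log w + p log(τ_f/τ_s)) / (1/τ_s − 1/τ_f)` — this analytic `t0`
(104.2 ms at the defaults) is the ground truth for every time-to-zero
test.  The default spatial size sits at the upper end of mouse RGC
receptive fields; it was chosen once so that a 75-µm checker grid clearly
resolves the Gaussian (a sub-checker receptive field would make the 2-D
fit degenerate and test nothing).

**Nonlinearity.** A saturating rectifier
`r(g) = min(r_max, a · max(g − θ, 0)) + baseline`, with the generator
signal `g` computed through the unit-norm filter so that `g` has unit
variance under the binary noise.  The rectifier has closed-form gain at
any generator value, which is what the gain-recovery checks use.

**Spiking and overdispersion.** With dispersion φ = 1, per-frame spike
counts are conditionally Poisson and spike times are uniform within their
frame.  For φ > 1 each frame's rate is multiplied by an independent gamma
variate with mean 1 (a gamma-mixed Poisson).  A frame-level multiplier
with fixed variance would *not* reproduce φ when counts are re-binned at
the 5-ms analysis bin — thinning a frame to a sub-bin scales the excess
variance by the occupancy fraction.  The package therefore defines φ as
the expected variance/mean ratio *at the 5-ms reference bin* and
calibrates the multiplier variance from the deterministic rate trace by
the law of total variance:

    ratio(bin) = 1 + v · Σ µ_b² / Σ µ_b,   µ_b = expected count per 5-ms bin,

solved for `v` given the target φ.  This leaves the mean rate and the STA
unbiased while raising count variance — matching the empirical picture of
signal-dependent noise sitting above the Poisson line with unchanged
receptive fields.  Bins straddling frame boundaries mix independent
multipliers, so measured ratios land within a few percent of φ rather
than exactly on it.

An absolute refractory period is available per cell
(`refractory_ms`), implemented as dead-time thinning.  The condition
presets leave it at zero: dead-time thinning preferentially deletes the
burst spikes that carry the overdispersion, deflating the measured
variance/mean ratio far below the configured φ (at 3 ms dead time a
φ = 1.8 cell measures ≈ 0.95).  Since the presets' φ values are anchored
to *measured* population ratios, the calibrated dispersion must survive
to the measurement — so refractoriness is reserved for analyses that
explicitly study it (autocorrelograms).

**Condition presets.** `condition_presets()` encodes qualitative
emulations of five cohorts — wild type, untreated degeneration, and
early/mid/late rescue timepoints — through four scales: gain
(1 / 0.55 / 0.91 / 0.98 / 0.67), dispersion φ (1 / 1.9 / 1 / 1 / 1.8),
integration-time scale, and sampling density.  The gain and φ anchors
follow the published population ratios between those cohorts (late ≈ 0.67
of WT gain; untreated ≈ 1.9× the WT variance/mean ratio); they are
emulations of trends, not fits to any recorded dataset, and the
information-rate ordering (late lowest) is *emergent* — lower gain plus
higher φ yields less information — not directly programmed.

## Receptive-field estimation

`compute_sta()` averages the stimulus over the `depth` frames preceding
each spike; a spike belongs to the frame on display at its time
(half-open intervals), and spikes inside the first `depth` frames are
excluded so every window is complete.  The default depth covers ~500 ms
(15 frames at 33 ms, 8 at 66 ms), which spans the temporal kernel's
support.  Lag ℓ is assigned time (ℓ + 0.5) × refresh — bin centers,
matching the uniform placement of spikes within frames.

`factorize_rank_one()` SVDs the (lag × checker) unfolding; the
separability variance fraction is σ₁²/Σσᵢ² and the screen admits cells
with fraction ≥ 0.60 *and* a biphasic temporal factor (a well-defined
zero crossing is required for time-to-zero).  The sign convention puts
the spatial map's dominant checker positive, so the unit-norm temporal
factor carries polarity (dominant lobe positive = ON).  "Biphasic"
requires an opposite-sign lobe of at least 5% of the dominant lobe's
magnitude — the cutoff is this package's operational choice for "well
defined"; it cleanly separates the simulator's biphasic kernels from
monophasic decays.

The statistics of the variance fraction are worth noting: an STA
estimated from n spikes carries i.i.d. noise of variance 1/n in each of
depth × checkers entries, so the fraction approaches 1 only when the
spike-triggered signal energy dominates `depth · n_checkers / n`.
Near-perfect separability readings therefore need ~10⁵ spikes on a small
grid; the population pipeline only needs to clear 0.60, which a 1500-s
mapping stimulus achieves for every preset.

**Spatial fit.** `fit_spatial_gaussian()` least-squares fits amplitude,
center, two sigmas, angle, and offset, initialized from the map's
dominant-sign moments (Nelder–Mead then BFGS).  Cells whose map has no
dominant lobe (peak < 3 × robust noise SD), whose fit fails, or whose
r² < 0.5 are flagged with a reason code and excluded from RF-size
summaries rather than silently fitted.  The reported geometry follows the
2-sigma-contour convention: axis lengths 4σ, effective diameter the
geometric mean of the two axis lengths, and area that of the circle with
this diameter.  A geometric mean of axes is a *length*, so turning it
into an area requires a convention; the circle-of-that-diameter choice is
used consistently and the raw sigmas and angle are always returned so any
other convention can be applied.

**Gain.** `estimate_nonlinearity()` bins the generator axis into
equal-count (quantile) bins — robust to the generator distribution's
shape, default 20 bins — and reports the mean rate per bin.  Gain is the
rate interpolated at 50% of the *peak generator value* (the x-axis
reading); the alternative (50% of peak rate) can be computed from the
returned curve.  Because the top quantile bin's center sits below the
extreme generator values, a query beyond the last center extends the line
through the last two bin means instead of clamping — clamping biases gain
low by several percent exactly in the regime the closed-form checks probe.

## Fidelity analyses

`count_matrix()` bins a spike train recorded over `n_repeats`
presentations into a repeat × bin count matrix (trailing partial bins
dropped).  `variance_mean()` summarizes signal-dependent noise as the
ratio of bin-averaged across-repeat variance (unbiased, n−1) to
bin-averaged mean — 1 for Poisson — and keeps the per-bin vectors for
variance-vs-mean scatter plots.

`direct_info()` implements the direct method: counts are clipped to a
small alphabet (binary by default — at 4–6-ms bins multiple spikes per
bin are rare, and the clip level is configurable and logged in the
result), grouped into non-overlapping words of 3–6 bins, and

    I = (H(R) − H(R|S)) / word duration,

with H(R) the plug-in entropy of the pooled word distribution and H(R|S)
the mean over word-aligned time slices of the across-repeat word entropy.
Slices are non-overlapping so their estimates are independent; no
extrapolation correction is applied by default (plug-in entropies are
reported as such), and the known plug-in bias bound
(|A|−1)/(2N ln 2) per slice is what the shuffled-control tests assert
against.  `ma_bound()` computes −log₂Σp², the coincidence-based bound;
the neural-coding literature calls this the "Ma Upper Bound" (an upper
bound on the entropy consistent with an observed coincidence rate) even
though, as an estimator applied to a distribution, it lower-bounds the
Shannon entropy — the package implements the stated formula and uses
only *proximity* between the plug-in noise entropy and its Ma bound to
select word parameters, so the naming question never affects a result.
Ties in the selection break toward the smallest bin, then the smallest
word.  The full parameter grid is returned as diagnostics so any other
selection rule can be applied afterwards.

`autocorrelogram()` histograms pairwise spike-time differences
(zero-lag self-pairs excluded) normalized to conditional rate, and
`cluster_cell_types()` k-means-partitions standardized feature rows
(receptive-field metrics plus autocorrelogram shape), sorting cells by id
before clustering so the partition cannot depend on input order.

## Nuclei counting

The counting chain is: optional local-contrast enhancement → fixed
threshold → constrained connected components → three-region sampling.

*Enhancement* (`local_contrast_enhance`) computes each pixel's local
z-score over a `window_px` neighborhood with summed-area tables (O(1) per
pixel), clamps negative z to zero and maps z linearly so that the
standard 8-bit threshold 104 corresponds to 2 local SDs above the local
mean, saturating at 255.  The fixed mapping makes counts invariant to
global intensity rescaling and removes smooth shading; the 2-SD
equivalence point was chosen so that, at realistic nucleus densities
(where nearby nuclei inflate the local SD), the threshold crossing sits
near a blob's half-maximum.  The window default (101 px ≈ 20 µm at
0.2 µm/px) is large relative to a nucleus so blob interiors are not
normalized away.  A constant image is returned unchanged.

*Threshold*: foreground is pixel ≥ 104 (inclusive), or ≥ 0.4 for images
already normalized to [0, 1].  The 8-bit value is taken as authoritative
(0.4 × 255 ≈ 102 would disagree by two gray levels).

*Detection* (`detect_nuclei`): 8-connected components (EBImage's
4-connected labeling plus a union-find merge of diagonal touches); a
component's width is the minor-axis length of its moment ellipse
(4 × √ of the smaller covariance eigenvalue) in µm.  Components narrower
than 2.1 µm are discarded; then any surviving component whose
nearest-edge distance (minimum pixel-center distance minus one pixel) to
another survivor is below 1.05 µm is discarded — both members of a
violating pair, since neither detection can be trusted.  Width is
measured on the thresholded mask, so it is the half-max width whenever
the threshold sits at half-max — which the synthetic generator guarantees
by calibrating blob amplitude to 2 × (104 − background).

*Regions* (`sample_regions`): three rectangles of exactly 1000 µm²
spanning the image height, centered at 25/50/75% of the width ("left,
center, right"); the mean of the three counts summarizes a retina.
Sub-threshold components that fail the width test by less than 20% feed
an out-of-focus heuristic: when they exceed 10% of accepted detections
the result carries a low-confidence flag (automated counts of this kind
typically miss ~5–10% of visible nuclei, which were historically rescued
by manual correction; the flag replaces that manual step).

## Statistics

Group comparisons are two-sided Kolmogorov–Smirnov tests (`stats::ks.test`;
exact null for n₁n₂ ≤ 10⁴) with Bonferroni correction over exactly the
family of comparisons requested in one call — the family is printed with
the results.  The mixed-effects contract is
`metric ~ condition (+ condition:sex + condition:cell_type) + (1 | retina)`
fitted by REML via `lme4::lmer`, with Wald-z fixed-effect tests — the
normal approximation is appropriate at this design's scale (tens of
retinas, tens-to-hundreds of cells each), and the calibration checks run
at 10 retinas × 50 cells confirm type-I error within [0.02, 0.08] at
α = 0.05.  Rank-deficient fixed-effect designs are refused with the
collinear columns named.

## What the generators do and do not emulate

The LNP simulator reproduces: the repeat protocol (10-s clips × 100), the
checkerboard geometries, space–time-separable receptive fields with
biphasic kernels, saturating contrast-response functions, Poisson and
calibrated super-Poisson count statistics, and population structure
(retinas, sexes, two kernel archetypes) with matched parameter draws
across conditions so preset scalings act deterministically on comparable
cells.  It does **not** emulate: nonlinear spatial subunits, spike-history
dependence beyond optional dead time, cross-cell correlations,
photoreceptor biophysics, light-level adaptation, or the spontaneous
oscillations of late-stage degeneration.  Passing tests therefore
demonstrate estimator correctness under the LNP assumptions, not that
real degenerated retina satisfies those assumptions.

The histology generator renders Gaussian-profile elliptical nuclei
(width = minor-axis FWHM) with max-compositing (nuclei are opaque, so
near-touching blobs keep distinct half-max contours), i.i.d. Gaussian
pixel noise, and planted constraint violators: narrow nuclei
(FWHM 1.2–1.7 µm) and close pairs (edge gap 0.6–0.8 µm, rendered
circular so the truth edge-gap computation is exact).
Constraint-satisfying nuclei are planted with ≥ 3 µm clearance — safely
inside the 1.05-µm rule, so truth labels are unambiguous under
measurement noise.  Planted densities (~25 nuclei per 100 × 40 µm field)
are sparser than the packed photoreceptor layer of healthy retina; the
generator is a test surface for the counting rules, not a tissue model,
and real sections additionally contain out-of-focus nuclei, nonuniform
staining and anisotropic shapes that it does not reproduce.

## Problem sizes and numerical choices

- Demo pipeline (`default_pipeline_config`): 5 conditions × 6 cells over
  2 retinas each, a 1500-s mapping stimulus on a 12 × 12 photopic board,
  and a 10-s × 100 repeat clip.  1500 s is the shortest mapping run at
  which every preset's cells clear the 60% separability screen with
  margin; real recordings are longer and larger.
- Simulator-closure checks use a single cell on an 8 × 8 board with ~10⁵
  spikes — the regime where the rank-one variance fraction exceeds 0.99
  (see the noise accounting above).
- Degenerate inputs are explicit errors: empty spike trains for the STA,
  all-zero kernels for the SVD, monophasic filters for time-to-zero,
  overlapping sampling regions, zero reference counts.
- All randomness flows through explicit integer seeds; stochastic entry
  points restore the caller's RNG state, and derived child seeds stay
  within 32-bit range.

## Known limitations

- The variance/mean calibration is exact only for analysis bins nested in
  stimulus frames; straddling bins deflate the measured ratio by a few
  percent.
- Plug-in entropies are biased at small repeat counts; the Ma-proximity
  selection mitigates but does not remove this, and no extrapolation is
  attempted.
- The moment-ellipse width underestimates the width of strongly concave
  (merged) components; the generator avoids creating them, real images
  may not.
- Mixed-model inference uses Wald z; with very few retinas per condition
  a Satterthwaite or parametric-bootstrap test would be preferable.
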
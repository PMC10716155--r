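# rgcfidelity

Analysis toolkit for retinal ganglion cell (RGC) physiology and retinal
histology in photoreceptor-degeneration and gene-therapy studies.  It is
aimed at labs that record RGC spike trains on multielectrode arrays under
checkerboard-noise stimulation and quantify how an intervention (e.g. the
timing of a genetic rescue in a retinitis-pigmentosa model) changes retinal
output, alongside photoreceptor survival measured in outer-nuclear-layer
(ONL) sections.

## What it computes

**Receptive fields and gain (reverse correlation).**  For a spike train
`R(t)` recorded under binary checkerboard noise `S`, the spike-triggered
average `STA(l) = E[S(t - l) | spike at t]` estimates the linear
spatiotemporal receptive field.  The STA is unfolded to a (lag x checker)
matrix and factorized by SVD; cells are *space–time separable* when the
rank-one term captures >= 60% of the STA variance and the temporal factor
is biphasic.  From the factors the package derives:

- **time-to-zero**: the interpolated zero crossing of the temporal filter,
  a proxy for integration time;
- **RF geometry**: a 2-D elliptical Gaussian fit to the spatial map; the
  2-sigma contour's axis lengths (4 sigma), their geometric mean as an
  effective diameter `d`, and the RF area `pi (d/2)^2`;
- **contrast-response function and gain**: the mean spike rate as a
  function of the generator signal `g = k * S` (unit-norm filter `k`),
  with gain defined as the rate at 50% of the peak generator value.

**Response fidelity on repeated stimuli.**  From a 10-s clip repeated
100 times: the across-repeat spike-count variance/mean ratio in 5-ms bins
(1 for a Poisson process; above 1 indicates signal-dependent noise), and
direct-method mutual information

    I(S; R) = H(R) - H(R | S)

over binary spike words of 3–6 bins of 4–6 ms, with the word parameters
chosen by proximity of the noise-entropy estimate to its coincidence-based
(Ma) bound `-log2 sum(p^2)`.

**ONL nuclei counting.**  Local-contrast enhancement by integral-image
z-scoring, a fixed 8-bit threshold (104), 8-connected components filtered
by minimum width (2.1 um, moment-ellipse minor axis) and minimum neighbor
edge distance (1.05 um, both members of a violating pair removed), counts
in three exact 1000-um^2 regions, and survival fractions against a
reference count.

**Statistics.**  Two-sided Kolmogorov–Smirnov comparisons with Bonferroni
correction, and a linear mixed-effects model with a per-retina random
intercept (`lme4`) so condition effects are tested against
experiment-to-experiment variability.

**Ground truth built in.**  A linear–nonlinear–Poisson (LNP) simulator
with space–time-separable cells, saturating-rectifier nonlinearities,
calibrated overdispersion (gamma-mixed Poisson with target variance/mean
ratio phi), and condition presets (WT / untreated / early / mid / late
treatment), plus a planted-nuclei image generator — every estimator in the
package is validated against these generators' known parameters.

## Worked example

```r
library(rgcfidelity)

## simulate a photopic recording: 75-um checkers, 33-ms refresh
clip   <- generate_checkerboard(30000, 8, 8, square_size_um = 75,
                                refresh_ms = 33, seed = 1)
cell   <- rgc_cell_params(center_um = c(290, 310), dispersion_phi = 1)
spikes <- simulate_spike_train(cell, clip, seed = 2)
spikes
#> Spike train 'sim': 13101 spikes over 990.0 s (13.23 spk/s)

sta <- factorize_rank_one(compute_sta(spikes, clip))
sta
#> STA for 'sim': 15 lags x 8 x 8 checkers, 13101 spikes
#>   rank-one variance fraction 0.918; space-time separable; polarity ON, biphasic

fit_spatial_gaussian(sta$spatial_map, 75)
#> Spatial RF: center (290, 311) um, sigma (57.4, 40.6) um, angle 3.10 rad
#>   2-sigma effective diameter 193 um, area 29302 um^2 (r2 = 0.992)

estimate_nonlinearity(spikes, clip, sta)
#> Contrast-response function (20 quantile bins): peak 92.4 spk/s, gain 85.8 spk/s at g = 1.94

time_to_zero(sta$temporal_filter, 33)$time_to_zero_ms   # truth: 104.2 ms
#> [1] 105.3486
```

The simulated cell is recovered almost exactly: the fitted RF center
(290, 311) um vs the planted (290, 310) um, sigmas (57, 41) vs (55, 40) um,
and a time-to-zero within ~1 ms of the kernel's analytic zero crossing.

Fidelity analyses run on a repeated clip:

```r
rep_clip   <- make_repeat_clip(generate_checkerboard(520, 12, 12, 75,
                               refresh_ms = 20, seed = 3), 10, 100)
noisy      <- rgc_cell_params(center_um = c(450, 450), dispersion_phi = 1.8)
rep_spikes <- simulate_spike_train(noisy, rep_clip, seed = 4)

variance_mean(count_matrix(rep_spikes, rep_clip, 5), 5)
#> Noise stats (5-ms bins, 100 repeats): mean rate 15.56 spk/s, variance/mean 1.836

select_word_params(rep_spikes, rep_clip)
#> Direct-method information (4-ms bins, 3-bin words): H = 0.716, H_noise = 0.522 bits/word -> 16.17 bits/s
```

The configured overdispersion (phi = 1.8) is read back as a variance/mean
ratio of 1.84, and the overdispersed cell transmits measurably less
information than a Poisson cell of the same rate.  Histology:

```r
img <- generate_onl_image(25, n_invalid_nuclei = 4, seed = 5)
count_nuclei(img, enhance = FALSE)
#> Nuclei count: 25 detections; region counts 6/8/6 (mean 6.7 +/- 0.7 SE)
```

All 25 constraint-satisfying planted nuclei are counted; the 4 planted
width-violators are rejected.  The full chain — stimuli, five-condition
population, receptive fields, fidelity, KS/Bonferroni summaries and the
mixed model — runs as one call:

```r
res <- run_pipeline(default_pipeline_config(seed = 1))
res$summaries$gain_spk_s$groups
```

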
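---
title: "Mapping spectral change and environmental risk from nighttime imagery: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping spectral change and environmental risk from nighttime imagery: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alanrisk)
```

## The problem and the measurement model

Outdoor lighting across Europe has been shifting from narrow-spectrum sodium
lamps to broad white LEDs. The panchromatic satellite record (the VIIRS
day/night band, sensitive from 480 to 920 nm) cannot observe this shift:
it integrates away the spectral information and is blind below 480 nm, where
the biologically most potent emissions grow. Colour (RGB) nighttime imagery
can, provided each frame is radiometrically calibrated and georeferenced and
the per-pixel band ratios are interpreted through synthetic photometry.

`alanrisk` implements that analysis as a pipeline with a fully synthetic,
ground-truthed data mode. Every quantity the pipeline must estimate —
per-pixel band radiances, colour ratios, cloud masks, control points,
instrument curves — is available as ground truth in synthetic mode, so each
stage is tested against what it should recover rather than against itself.

## Synthetic photometry

A spectrum is sampled on a 1-nm grid over 380–780 nm. The band signal of a
channel is the trapezoidal integral of spectral power times channel
sensitivity; colour ratios (B/G, G/R, R/G) are ratios of band signals and
are invariant to overall intensity. Biological indices are ratio-of-ratio
integrals: the action-weighted content per unit photopic content, normalised
by the same quantity for a broad reference illuminant, so the reference
scores exactly 1 and a spectrum with no power inside the action band scores
(near) 0.

Choices that matter, and their defaults:

* **Camera channel curves.** Measured sensitivities of the DSLR cameras
  behind the source imagery are not published; the default camera uses three
  Gaussian approximations (B: 460/30 nm, G: 530/35 nm, R: 600/40 nm,
  mean/sigma, peak-normalised). Measured curves can be substituted from CSV
  (`read_camera_csv()`); every ratio-based result is conditional on the
  curves in use. One consequence of these defaults: a pure low-pressure
  sodium line lands at B/G ≈ 0.0004 and R/G ≈ 4.0 — deep in the "orange"
  corner, though short of the R/G > 6 outlier bound.
* **Action spectra.** Tabulated analytic approximations ship in
  `inst/extdata`: a blue-peaked Gaussian (464/38 nm) for melatonin
  suppression, the standard photopic and scotopic luminosity approximations
  (the scotopic curve serves as the blue-weighted star-visibility curve),
  and a 400/60 nm Gaussian with near-UV support for insect phototaxis. All
  are configurable through the same CSV format.
* **Reference illuminant.** A 6500 K Planckian curve ("D65-like"),
  peak-normalised; it anchors index = 1 and makes the identity testable.
* **Lamp library.** Modelled spectra (line lists for LPS/HPS/mercury,
  Gaussian-mixture continua for fluorescent and metal halide, two-lobe
  blue-peak-plus-phosphor white LEDs at 3000/4000 K CCT), each normalised to
  unit power, plus seeded pairwise mixtures — at least 20 members spanning
  the classes.

### Ratio-index relationships

`fit_ratio_index_curve()` refits the mapping from a colour ratio to an index
over the lamp library: quadratic in the ratio for B/G predictors and
exponential `a·b^ratio` for G/R predictors, mirroring the functional forms
of the published intensity models. Confidence intervals come from a
nonparametric bootstrap over library members (1000 replicates by default,
percentile intervals, seeded). The published coefficient values of the
ratio→MSI/SLI relationships are not available, so index maps produced here
are internally consistent (checked against direct synthetic photometry) but
not numerically anchored to the published index medians; the three published
intensity models (their coefficients and CIs) are used verbatim and are
checked at their printed anchor values.

A note on the bootstrap-coverage test: with noise σ = 0.01 each
coefficient's 95% CI covers its true value in well over 90% of replicates.
Joint coverage of all intervals simultaneously is necessarily lower
(≈ 0.95^p), so the tests check per-coefficient coverage.

## The synthetic scene

`make_lamp_maps()` draws city footprints as Gaussian-decay emission blobs
(log-normal peak radiances, median ≈ 40 nW cm⁻² sr⁻¹) on a 500-m grid in
EPSG:3035. Epoch 1 mixes high-pressure sodium (45–70%) with low-pressure
sodium, mercury and fluorescent light, per city; epoch 2 reassigns the
sodium weight of a seeded random fraction `epoch_shift` of lit pixels to
white LED (3000/4000 K split). `render_viirs()` integrates each pixel's
mixture spectrum against a 480–920 nm boxcar.

`render_frame()` is the forward instrument model: per-band scene radiance ×
exposure × ISO gain × lens/window transmittance × per-band atmospheric
transmittance^airmass, occluding clouds (3% transmittance plus a faint
0.02 nW diffuse glow), reference point sources, channel crosstalk, radial
vignetting, photon + read noise, and a linear-then-power sensor response
rolling off above a knee at 80% of full well. Ground truth for everything
rides along in `$truth`.

Design decisions the epoch comparison relies on, and why:

* **Clouds occlude rather than brighten.** City light seen from above
  through cloud is attenuated, which is also what makes the
  dark-versus-VIIRS detection heuristic meaningful. The faint glow term is
  kept small enough that an occluded pixel's G radiance stays well below
  0.2× its VIIRS value wherever the VIIRS mask would retain the pixel.
* **Reference sources sit above the atmosphere.** Calibration stars are
  imaged without atmospheric extinction (the spacecraft is above the
  atmosphere; the ground scene is not), keeping the instrumental-constant
  estimate independent of the atmospheric correction. In synthetic frames
  they are placed over dark sky with non-overlapping photometry apertures,
  as real calibration fields would be chosen.
* **One instrument calibration, shared acquisition plan.** The instrumental
  constants are estimated once, from a dedicated calibration acquisition,
  and applied to all frames of both epochs — per-frame re-estimation would
  inject a per-epoch scale error that a two-epoch median comparison cannot
  distinguish from a real change. Likewise the acquisition plan (frame
  tiling, angles, optics, settings) and the cloud realisation per frame
  position are shared between epochs, with only timestamps, noise and
  control-point jitter differing: the epoch contrast should measure the
  scene's spectral shift, not sampling differences. Real mosaics do carry
  coverage differences between epochs; this generator deliberately removes
  them so that a zero-shift scene yields a null result.
* **Auto-exposure.** Exposure time is set per frame so the brightest window
  pixel sits at the linearity knee, as a photographer protecting highlights
  would; the nonlinear regime above the knee is still exercised (epoch-2
  scenes can exceed the epoch-1-planned knee), while hard saturation —
  whose noise-flipped boundary pixels otherwise churn the valid set between
  epochs — essentially disappears.

## Calibration, mosaicking, masking

The correction chain order is fixed: linearity → flat field → spectral
characterisation → photometric/radiometric → atmospheric → cloud mask;
`calibrate_frame()` applies it. In synthetic mode the instrument curves are
known exactly (they are laboratory characterisations in the real workflow)
and only the per-channel instrumental constants are estimated, by aperture
photometry (3-px aperture, 5–7-px annulus median background, median ratio
over ≥ 3 usable sources; saturated sources are excluded).

Georeferencing fits the frame-to-grid mapping from control points — affine
(≥ 4 points) or thin-plate spline with the `r² log r` kernel (≥ 6 points) —
and resamples nearest-neighbour by default so band ratios never blend across
source pixels. The control-point residual RMSE is reported; with the default
4-px jitter it reproduces the ~4-px georeferencing error the analysis
assumes, which is also why all inference is distribution-wise per epoch
rather than per pixel.

Compositing is winner-takes-all under a lexicographic precedence: lower
observation angle, then longer focal length, then smaller offset from frame
centre, then (post-epoch policy only) more recent acquisition; remaining
ties break on frame ID, making the mosaic independent of input order. The
listed preferences come from the source methodology, which does not state a
combination rule; lexicographic ordering with angle dominant is one
consistent, reproducible reading.

Ratio grids are masked, in any order (the operations commute on the valid
set): `unlit` (any nonpositive band), `outlier` (B/G > 1.2 or G/R > 1.2 or
R/G > 6 — "exceeds" is read as strict inequality, and the or-combination is
the default with a conjunctive switch, since the prose rule is ambiguous),
and `below_viirs_threshold` (VIIRS < 0.5 nW cm⁻² sr⁻¹, guarding against
skyglow-dominated pixels). Masked pixels keep the first reason that
invalidated them and are excluded from every downstream statistic.

## Change analysis

`compare_epochs()` reports type-7 (linear interpolation) medians and IQRs,
a two-group Kruskal–Wallis rank test with tie correction (kept in
chi-squared form with df = 1 to match the reporting convention of the
source analyses), and the percent change of medians. Pixels are treated as
independent samples; spatial autocorrelation makes the p-values optimistic,
which is documented rather than corrected. `zonal_summary()` aggregates
valid pixels per region polygon (pixel-centre rule) per epoch; regions with
no valid pixels are flagged, never dropped.

## Problem sizes and numerical choices

The shipped tests exercise the full pipeline at 120–320 px grids with 4–9
frames per epoch and 5–24 cities; the two-epoch scenario checks run at
320 × 320 (≈ 33,000 valid pixels per epoch), where the null scenario's
median changes settle well inside ±1% and Kruskal–Wallis p-values are
uniform. Key tolerances: calibration round-trip median per-pixel radiance
error ≤ 5% and pooled ratio-median error ≤ 2% on valid (VIIRS ≥ 0.5) pixels;
pipeline colour ratios of pure lamp classes within 2% of direct synthetic
photometry; exact-recovery fits to 1e-6. Degenerate inputs are errors, not
silent results: empty samples, all-identical pooled values (H = 0, p = 1
with a warning), rank-deficient fits, collinear control points, fewer than
three usable calibration sources, missing CRS declarations.

## What the synthetic mode does and does not show

The generator reproduces the statistical structure the analysis assumes —
a spatially mixed lamp population shifting toward LED, instrumentally
distorted acquisitions, panchromatic masking — but not urban morphology,
directional emission, atmospheric radiative transfer of skyglow, aerosol
variability, or the archive's uneven frame quality and manual cloud
inspection. Passing tests therefore demonstrate that the estimators recover
known ground truth under the stated instrument and noise model, not that
real-archive calibration reaches the same accuracy. The index maps are
internally consistent against the package's own lamp library; absolute index
levels depend on the action spectra and camera curves in use.
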
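# alanrisk

Artificial light at night (ALAN) is shifting across Europe from
narrow-spectrum sodium street lighting toward broad white LEDs. Panchromatic
satellite sensors such as the VIIRS day/night band (sensitive 480–920 nm)
cannot see this shift — they are blind to exactly the blue emissions that
matter most for biology — so colour imagery is needed to map where the
spectral composition of nighttime lighting is changing and what that implies
for ecosystems and people.

`alanrisk` implements, as a tested and reusable R pipeline, the analysis that
turns multi-epoch nighttime RGB imagery into:

* calibrated radiance mosaics (nW cm⁻² sr⁻¹) on a 500-m equal-area grid
  (ETRS89-LAEA), built from individually corrected camera frames;
* masked **B/G, G/R, R/G colour-ratio maps** — spectral class proxies;
* **VIIRS-corrected band intensities** and **environmental-risk index maps**:
  melatonin suppression (MSI), star visibility (SLI) and insect phototaxis;
* **epoch-change statistics**: medians, IQRs, Kruskal–Wallis rank tests,
  percent changes, and zonal summaries over country or species-range
  polygons.

A ground-truthed synthetic scene generator (sodium-dominated epoch 1 →
LED-converted epoch 2, with camera nonlinearity, vignetting, channel
crosstalk, atmospheric extinction, clouds, noise, and ~4-px georeferencing
error) stands in for real acquisitions, so every stage is testable end to
end without downloads.

## The models at the core

**Synthetic photometry.** For a source spectrum *S(λ)* and channel
sensitivity *R_c(λ)*, the band signal is the trapezoidal integral
∫ S(λ) R_c(λ) dλ; colour ratios are ratios of band signals. Biological
indices are ratio-of-ratio integrals against an action spectrum *A(λ)* and
the photopic curve *V(λ)*, normalised so a D65-like reference scores 1:

    index(S) = [∫S·A / ∫S·V] / [∫ref·A / ∫ref·V]

**VIIRS-corrected intensities.** Band intensities are estimated from the
panchromatic VIIRS radiance and a colour ratio via fitted relationships
(95% bootstrap CIs on the coefficients):

    G_VIIRS = VIIRS · 0.21 · 1.5^(G/R)
    B_VIIRS = VIIRS · (−0.03 + 0.6·(B/G) + 1.3·(B/G)²)
    P_I     = VIIRS · 0.23 · 0.21^(G/R)

**Per-frame calibration chain** (fixed order): decodification → linearity →
flat field → spectral characterisation → photometric calibration against
reference point sources → radiometric (settings) correction → atmospheric
correction → cloud masking. Frames are georeferenced from ground control
points (affine or thin-plate spline) and composited winner-takes-all with
lexicographic precedence (lower nadir angle, longer focal length, nearer
frame centre, more recent — the last under the post-epoch policy only).
Ratio grids are masked where B/G or G/R exceeds 1.2 or R/G exceeds 6, and
where VIIRS radiance is below 0.5 nW cm⁻² sr⁻¹.

## Worked example

```r
library(alanrisk)

# lamp spectra and their camera colour ratios / melatonin indices
color_ratios(lamp_spd("hps"))
#> b_over_g g_over_r r_over_g
#>    0.223    0.382    2.618
spectral_index(lamp_spd("hps"),       action_spectrum("melatonin_suppression"))
#> [1] 0.145
spectral_index(lamp_spd("led_4000k"), action_spectrum("melatonin_suppression"))
#> [1] 0.537

# full two-epoch synthetic run: half of the lit pixels convert to LED
cfg <- pipeline_config(grid_shape = c(160, 160), n_cities = 8,
                       frames_per_epoch = 6, epoch_shift = 0.5, seed = 42)
res <- run_pipeline(cfg)
res$comparisons$b_over_g
#> b_over_g: pre median 0.3069 (IQR 0.03603, n 9074) -> post median 0.3956 (IQR 0.1726, n 9014)
#>   change +28.9%, Kruskal-Wallis chi2 = 3274.12, df = 1, p = 0
res$comparisons$msi
#> msi: pre median 0.2239 (IQR 0.04114, n 9074) -> post median 0.3376 (IQR 0.2436, n 9014)
#>   change +50.8%, Kruskal-Wallis chi2 = 3274.12, df = 1, p = 0
```

The B/G ratio and the melatonin suppression index both rise between the
epochs — whiter, bluer light — while a run with `epoch_shift = 0` shows
changes statistically indistinguishable from zero. `plot(res$mosaics$epoch2)`
draws a mosaic band; `res$zonal` (with `n_regions > 0`) tabulates per-region
change.

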
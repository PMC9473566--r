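Package: alanrisk
Title: Spectral Change and Environmental Risk Mapping for Nighttime Lighting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts multi-epoch nighttime RGB imagery into calibrated radiance
    mosaics, spectral colour-ratio maps, and maps of environmental-risk indices
    (melatonin suppression, star visibility, insect phototaxis). Includes a
    synthetic-photometry core for lamp spectra, a ground-truthed synthetic scene
    generator emulating the sodium-to-LED transition of European street lighting,
    the per-frame radiometric calibration chain (linearity, flat field, spectral
    characterisation, photometric and atmospheric correction, cloud masking),
    precedence-based mosaicking with thin-plate-spline georeferencing, outlier and
    VIIRS-threshold masking of colour-ratio grids, VIIRS-corrected band-intensity
    estimators, and epoch-change statistics (medians, IQRs, Kruskal-Wallis tests,
    zonal summaries over region and species-range polygons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    mgcv,
    pracma
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
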
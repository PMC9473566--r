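# per-frame correction chain: linearity -> flat field -> spectral
# characterisation -> photometric/radiometric calibration -> atmospheric
# correction -> cloud masking. The chain order is fixed; calibrate_frame()
# is the single driver that applies it.

#' Calibration model for a camera/instrument
#'
#' Holds everything the correction chain needs: the sensor linearity curve
#' (knee + power roll-off parameters), the flat-field raster (or radial
#' vignette polynomial), the 3x3 channel crosstalk matrix, per-channel
#' instrumental constants (radiance units per count at reference settings;
#' `NA` until estimated from reference sources), per-band atmospheric
#' transmittance, and the reference ISO.
#'
#' In synthetic mode the curves are known exactly (they are laboratory
#' characterisations in the real workflow); only the instrumental constants
#' are estimated in-flight, from reference point sources.
#'
#' @param nonlinearity List with `fullwell`, `knee_frac`, `power` (see
#'   [distortion_config()]).
#' @param flatfield Flat-field raster in (0, 1], or `NULL` to derive one from
#'   `vignette` for each frame shape.
#' @param vignette Radial polynomial coefficients `c(a2, a4)` used when
#'   `flatfield` is `NULL`.
#' @param crosstalk 3x3 channel mixing matrix (rows nonnegative, invertible).
#' @param constants Per-channel instrumental constants, named r/g/b, or `NA`.
#' @param t_atm Per-band atmospheric transmittance in (0, 1], named r/g/b.
#' @param ref_iso Reference ISO for settings normalisation.
#' @param max_airmass Cap on `1 / cos(angle)`.
#' @return Object of class `calibration_model`.
#' @export
calibration_model <- function(nonlinearity = list(fullwell = 16383,
                                                  knee_frac = 0.8,
                                                  power = 0.6),
                              flatfield = NULL, vignette = c(0.30, 0.15),
                              crosstalk = diag(3),
                              constants = c(r = NA, g = NA, b = NA),
                              t_atm = c(r = 1, g = 1, b = 1),
                              ref_iso = 200, max_airmass = 3) {
  stopifnot(all(t_atm > 0), all(t_atm <= 1), all(crosstalk >= 0))
  if (!is.null(flatfield) && any(flatfield <= 0))
    stop("flat field must be strictly positive")
  if (abs(det(crosstalk)) < 1e-12) stop("crosstalk matrix is singular")
  structure(list(nonlinearity = nonlinearity, flatfield = flatfield,
                 vignette = vignette, crosstalk = crosstalk,
                 constants = constants, t_atm = t_atm, ref_iso = ref_iso,
                 max_airmass = max_airmass),
            class = "calibration_model")
}

#' Calibration model matching a distortion configuration
#'
#' Builds the "laboratory characterisation" of a synthetic instrument: the
#' same linearity, vignette, crosstalk and atmospheric parameters the
#' renderer used, with instrumental constants left to be estimated from the
#' frame's reference sources.
#'
#' @param distortions A [distortion_config()].
#' @return A [calibration_model].
#' @export
calibration_model_from_config <- function(distortions) {
  calibration_model(nonlinearity = distortions$nonlinearity,
                    vignette = distortions$vignette,
                    crosstalk = distortions$crosstalk,
                    t_atm = distortions$t_atm,
                    ref_iso = distortions$ref_iso,
                    max_airmass = distortions$max_airmass)
}

frame_mask <- function(frame) {
  if (is.null(frame$mask)) matrix(0L, dim(frame$counts)[1],
                                  dim(frame$counts)[2]) else frame$mask
}

iso_gain <- function(geom, model) geom$iso / model$ref_iso

#' Linearity correction
#'
#' Maps counts through the inverse sensor response: counts below the knee are
#' unchanged; above it the power roll-off is inverted. Pixels at or beyond
#' the response of the full well are flagged `saturated` in the mask.
#'
#' @param frame A `raw_frame`.
#' @param model A [calibration_model].
#' @return The frame with linearised counts and updated mask.
#' @export
correct_linearity <- function(frame, model) {
  nl <- model$nonlinearity
  counts <- frame$counts
  mask <- frame_mask(frame)
  knee <- nl$knee_frac * nl$fullwell
  if (is.finite(knee) && nl$power < 1) {
    sat_level <- knee * (nl$fullwell / knee)^nl$power
    sat <- apply(counts >= sat_level * 0.999, c(1, 2), any)
    mask[sat & mask == 0L] <- mask_codes()[["saturated"]]
    hi <- counts > knee
    counts[hi] <- knee * (counts[hi] / knee)^(1 / nl$power)
  }
  frame$counts <- counts
  frame$mask <- mask
  frame
}

#' Flat-field / vignetting correction
#'
#' Divides every channel by the flat-field raster (taken from the model, or
#' derived from its radial vignette polynomial for the frame's shape).
#'
#' @inheritParams correct_linearity
#' @return The frame with flat-fielded counts.
#' @export
correct_flatfield <- function(frame, model) {
  d <- dim(frame$counts)
  ff <- model$flatfield
  if (is.null(ff)) ff <- vignette_raster(d[1:2], model$vignette)
  if (!identical(dim(ff), d[1:2])) stop("flat field shape mismatch")
  if (any(ff <= 0)) stop("flat field must be strictly positive")
  frame$counts <- frame$counts / as.vector(ff)
  frame$mask <- frame_mask(frame)
  frame
}

#' Spectral characterisation (channel crosstalk inversion)
#'
#' Multiplies each pixel's channel vector by the inverse crosstalk matrix.
#' Negative corrected counts are clipped to zero.
#'
#' @inheritParams correct_linearity
#' @return The frame with crosstalk-corrected counts.
#' @export
spectral_characterize <- function(frame, model) {
  if (abs(det(model$crosstalk)) < 1e-12)
    stop("crosstalk matrix is singular")
  d <- dim(frame$counts)
  flat <- matrix(frame$counts, prod(d[1:2]), 3)
  corrected <- flat %*% t(solve(model$crosstalk))
  n_neg <- sum(corrected < 0)
  corrected[corrected < 0] <- 0
  frame$counts <- array(corrected, d)
  frame$mask <- frame_mask(frame)
  attr(frame, "n_negative_clipped") <- n_neg
  frame
}

#' Photometric calibration from reference point sources
#'
#' Estimates the per-channel instrumental constant (radiance units per count
#' at reference settings) from point sources of known radiance via aperture
#' photometry: a 3-pixel-radius aperture sum with annulus (5-7 px) median
#' background, normalised by exposure, ISO gain and lens transmittance. The
#' constant is the robust (median) ratio across usable sources; sources
#' touching saturated pixels are excluded, and fewer than 3 usable sources is
#' an error (the frame is uncalibratable).
#'
#' @param frame A `raw_frame` after linearity, flat-field and spectral
#'   correction.
#' @param reference_sources Data frame with `row`, `col` and known radiances
#'   `r`, `g`, `b` (defaults to the frame's ground-truth star table).
#' @param model A [calibration_model].
#' @return Named numeric vector of per-channel constants (`r`, `g`, `b`).
#' @export
photometric_calibrate <- function(frame,
                                  reference_sources = frame$truth$stars,
                                  model) {
  if (is.null(reference_sources) || nrow(reference_sources) < 3)
    stop("frame uncalibratable: fewer than 3 reference sources")
  d <- dim(frame$counts)
  mask <- frame_mask(frame)
  geom <- frame$geometry
  norm <- geom$exposure_s * iso_gain(geom, model) * geom$lens_t
  offs <- expand.grid(dr = -7:7, dc = -7:7)
  rad <- sqrt(offs$dr^2 + offs$dc^2)
  ap <- rad <= 3
  ann <- rad >= 5 & rad <= 7
  ratios <- matrix(NA_real_, nrow(reference_sources), 3)
  for (i in seq_len(nrow(reference_sources))) {
    r <- reference_sources$row[i]; c <- reference_sources$col[i]
    rr <- r + offs$dr; cc <- c + offs$dc
    inb <- rr >= 1 & rr <= d[1] & cc >= 1 & cc <= d[2]
    flat <- (cc - 1) * d[1] + rr
    if (any(mask[flat[inb & ap]] == mask_codes()[["saturated"]])) next
    for (b in 1:3) {
      plane <- frame$counts[, , b]
      bg <- stats::median(plane[flat[inb & ann]])
      sig <- sum(plane[flat[inb & ap]] - bg)
      if (sig > 0)
        ratios[i, b] <- reference_sources[[c("r", "g", "b")[b]]][i] * norm / sig
    }
  }
  usable <- rowSums(is.finite(ratios)) == 3
  if (sum(usable) < 3)
    stop("frame uncalibratable: fewer than 3 usable reference sources")
  constants <- apply(ratios[usable, , drop = FALSE], 2, stats::median)
  names(constants) <- c("r", "g", "b")
  constants
}

#' Radiometric (settings) correction
#'
#' Converts counts to radiance: `radiance = counts * constant /
#' (exposure * ISO-gain * lens transmittance)`, in nW cm-2 sr-1.
#'
#' @param frame A corrected `raw_frame`.
#' @param constants Per-channel instrumental constants (from
#'   [photometric_calibrate()]).
#' @param model A [calibration_model].
#' @return Object of class `radiance_frame`: `radiance` array, `mask`,
#'   `geometry`, `cps`, `truth`.
#' @export
radiometric_correct <- function(frame, constants, model) {
  geom <- frame$geometry
  for (f in c("exposure_s", "iso", "lens_t"))
    if (is.null(geom[[f]]) || !is.finite(geom[[f]]))
      stop("missing acquisition metadata field: ", f)
  norm <- geom$exposure_s * iso_gain(geom, model) * geom$lens_t
  d <- dim(frame$counts)
  rad <- frame$counts *
    rep(constants[c("r", "g", "b")] / norm, each = prod(d[1:2]))
  structure(list(radiance = rad, mask = frame_mask(frame), geometry = geom,
                 cps = frame$cps, truth = frame$truth),
            class = "radiance_frame")
}

#' Atmospheric correction
#'
#' Divides each band by its transmittance raised to the airmass
#' (`1 / cos(observation angle)`, capped at the model's maximum).
#'
#' @param frame A `radiance_frame`.
#' @param model A [calibration_model].
#' @return The corrected `radiance_frame`.
#' @export
atmospheric_correct <- function(frame, model) {
  airmass <- min(1 / cos(frame$geometry$angle_deg * pi / 180),
                 model$max_airmass)
  d <- dim(frame$radiance)
  frame$radiance <- frame$radiance /
    rep(model$t_atm[c("r", "g", "b")]^airmass, each = prod(d[1:2]))
  frame
}

#' Cloud masking
#'
#' Either applies a supplied cloud mask, or flags pixels that look dark
#' relative to a co-located VIIRS raster: a cloud between the camera and the
#' ground occludes city light that the (cloud-free composite) VIIRS raster
#' still shows, so pixels whose G radiance falls below `frac` times the VIIRS
#' value are flagged `cloud`.
#'
#' @param frame A `radiance_frame`.
#' @param mask Optional logical matrix of cloud pixels (ground truth or
#'   manual).
#' @param viirs Optional [alan_grid] with layer `viirs` covering the scene
#'   grid; the frame's window is extracted via its ground-truth origin.
#' @param frac Dark-vs-VIIRS threshold fraction (default 0.2).
#' @return The frame with cloud pixels flagged in its mask.
#' @export
mask_clouds <- function(frame, mask = NULL, viirs = NULL, frac = 0.2) {
  if (is.null(mask) && is.null(viirs))
    stop("either a cloud mask or a VIIRS raster must be supplied")
  d <- dim(frame$radiance)
  fmask <- frame$mask
  if (!is.null(mask)) {
    if (!identical(dim(mask), d[1:2])) stop("cloud mask shape mismatch")
    cl <- mask
  } else {
    o <- frame$truth$origin_px
    v <- viirs$layers$viirs[o[1]:(o[1] + d[1] - 1), o[2]:(o[2] + d[2] - 1)]
    cl <- frame$radiance[, , 2] < frac * v
  }
  fmask[cl & fmask == 0L] <- mask_codes()[["cloud"]]
  frame$mask <- fmask
  frame
}

#' Full per-frame calibration chain
#'
#' Applies the fixed correction order: linearity, flat field, spectral
#' characterisation, photometric calibration (from reference sources, unless
#' constants are already present in the model), radiometric correction,
#' atmospheric correction, cloud masking.
#'
#' @param frame A `raw_frame`.
#' @param model A [calibration_model].
#' @param reference_sources Passed to [photometric_calibrate()].
#' @param cloud_mask,viirs,cloud_frac Passed to [mask_clouds()]; if both
#'   `cloud_mask` and `viirs` are `NULL` the cloud step is skipped.
#' @return A `radiance_frame`.
#' @export
calibrate_frame <- function(frame, model,
                            reference_sources = frame$truth$stars,
                            cloud_mask = NULL, viirs = NULL,
                            cloud_frac = 0.2) {
  frame <- correct_linearity(frame, model)
  frame <- correct_flatfield(frame, model)
  frame <- spectral_characterize(frame, model)
  constants <- model$constants
  if (any(!is.finite(constants)))
    constants <- photometric_calibrate(frame, reference_sources, model)
  rframe <- radiometric_correct(frame, constants, model)
  rframe <- atmospheric_correct(rframe, model)
  if (!is.null(cloud_mask) || !is.null(viirs))
    rframe <- mask_clouds(rframe, mask = cloud_mask, viirs = viirs,
                          frac = cloud_frac)
  rframe$constants <- constants
  rframe
}
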
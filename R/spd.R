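#' Spectral power distribution
#'
#' A wavelength-sampled emission spectrum (relative spectral radiance per nm),
#' the root object of the synthetic-photometry machinery: band signals, colour
#' ratios and biological indices are all integrals of an `spd` against a
#' sensitivity or action curve.
#'
#' @param wavelength_nm Numeric vector of strictly increasing wavelengths (nm).
#'   The nominal working range is 380-780 nm with step <= 5 nm.
#' @param power Nonnegative spectral power, same length as `wavelength_nm`
#'   (relative units).
#' @param name Optional label (e.g. a lamp class).
#' @return An object of class `spd`.
#' @export
spd <- function(wavelength_nm, power, name = NULL) {
  wavelength_nm <- as.numeric(wavelength_nm)
  power <- as.numeric(power)
  if (length(wavelength_nm) != length(power))
    stop("wavelength and power must have the same length")
  if (length(wavelength_nm) < 2L)
    stop("an spd needs at least 2 samples")
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelengths must be strictly increasing")
  if (any(!is.finite(wavelength_nm)) || any(!is.finite(power)))
    stop("spd values must be finite")
  if (any(power < 0))
    stop("spectral power must be nonnegative")
  structure(list(wavelength = wavelength_nm, power = power, name = name),
            class = "spd")
}

#' @export
print.spd <- function(x, ...) {
  cat(sprintf("<spd%s: %d samples, %g-%g nm, total power %.4g>\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              pracma::trapz(x$wavelength, x$power)))
  invisible(x)
}

#' @export
plot.spd <- function(x, ...) {
  graphics::plot(x$wavelength, x$power, type = "l",
                 xlab = "wavelength (nm)", ylab = "relative power",
                 main = x$name, ...)
  invisible(x)
}

#' Linear combination of spectra
#'
#' Mixes spectra on the union of their wavelength grids (power outside a
#' spectrum's support is taken as 0). Weights must be nonnegative.
#'
#' @param spds List of [spd] objects.
#' @param weights Nonnegative numeric weights, one per spectrum.
#' @param name Optional label for the mixture.
#' @return An [spd].
#' @export
mix_spd <- function(spds, weights, name = NULL) {
  stopifnot(length(spds) == length(weights), all(weights >= 0))
  wl <- sort(unique(unlist(lapply(spds, function(s) s$wavelength))))
  p <- rep(0, length(wl))
  for (i in seq_along(spds)) {
    s <- spds[[i]]
    p <- p + weights[i] * stats::approx(s$wavelength, s$power, xout = wl,
                                        yleft = 0, yright = 0)$y
  }
  spd(wl, p, name = name)
}

#' Camera spectral response
#'
#' Three channel sensitivity curves (R, G, B), each nonnegative and
#' peak-normalised to 1, with channel sensitivity peaks ordered
#' B < G < R in wavelength.
#'
#' @param wavelength_nm Common wavelength grid (nm).
#' @param r,g,b Channel sensitivities on that grid.
#' @return An object of class `camera_response`: a named list of per-channel
#'   sensitivity curves (`$r`, `$g`, `$b`), each a list with `wavelength` and
#'   `sensitivity`.
#' @export
camera_response <- function(wavelength_nm, r, g, b) {
  chans <- list(r = r, g = g, b = b)
  peaks <- numeric(3)
  out <- list()
  for (i in seq_along(chans)) {
    s <- as.numeric(chans[[i]])
    if (length(s) != length(wavelength_nm)) stop("channel grid mismatch")
    if (any(s < 0)) stop("sensitivities must be nonnegative")
    if (max(s) <= 0) stop("channel has zero sensitivity everywhere")
    s <- s / max(s)
    out[[names(chans)[i]]] <- list(wavelength = as.numeric(wavelength_nm),
                                   sensitivity = s)
    peaks[i] <- wavelength_nm[which.max(s)]
  }
  if (!(peaks[3] < peaks[2] && peaks[2] < peaks[1]))
    stop("channel sensitivity peaks must be ordered B < G < R in wavelength")
  structure(out, class = "camera_response")
}

#' Default camera response
#'
#' Gaussian approximations to a DSLR's channel sensitivities:
#' B centred at 460 nm (sigma 30), G at 530 nm (sigma 35), R at 600 nm
#' (sigma 40). Measured curves can be substituted via
#' [read_camera_csv()]; all ratio-based results are curve-dependent, so the
#' curves in use are part of any result's provenance.
#'
#' @param wavelength_nm Wavelength grid, default 380-780 nm step 1.
#' @return A [camera_response].
#' @export
default_camera <- function(wavelength_nm = 380:780) {
  gauss <- function(mu, sigma) exp(-(wavelength_nm - mu)^2 / (2 * sigma^2))
  camera_response(wavelength_nm,
                  r = gauss(600, 40), g = gauss(530, 35), b = gauss(460, 30))
}

#' Action spectrum
#'
#' A nonnegative, peak-normalised biological or visual weighting curve.
#' Bundled curves (see `inst/extdata`) are analytic approximations to the
#' standard published curves: `melatonin_suppression` (blue-peaked, ~464 nm),
#' `photopic` (CIE daytime luminosity), `scotopic_starlight` (dark-adapted,
#' blue-shifted; used for the star light index), and `phototaxis`
#' (insect attraction, peaked near 400 nm with support into the near-UV).
#'
#' @param name One of `"melatonin_suppression"`, `"photopic"`,
#'   `"scotopic_starlight"`, `"phototaxis"`, or a path to a 2-column CSV
#'   (`wavelength_nm,value`, header required).
#' @return A list of class `action_spectrum` with `name`, `wavelength`,
#'   `weight`.
#' @export
action_spectrum <- function(name) {
  builtin <- c("melatonin_suppression", "photopic", "scotopic_starlight",
               "phototaxis")
  path <- if (name %in% builtin) {
    system.file("extdata", paste0(name, ".csv"), package = "alanrisk",
                mustWork = TRUE)
  } else name
  tab <- utils::read.csv(path)
  w <- as.numeric(tab[[2]])
  if (any(w < 0)) stop("action spectrum weights must be nonnegative")
  wl <- as.numeric(tab[[1]])
  if (any(wl < 300) || any(wl > 800))
    stop("action spectrum support must lie within 300-800 nm")
  structure(list(name = name, wavelength = wl, weight = w / max(w)),
            class = "action_spectrum")
}

#' Reference illuminant
#'
#' A broad daylight-like (D65-like) spectrum used to anchor spectral indices:
#' by construction [spectral_index()] of the reference against itself is 1.
#' The bundled default is a 6500 K Planckian curve, peak-normalised.
#'
#' @param path Optional CSV path overriding the bundled spectrum.
#' @return An [spd].
#' @export
reference_illuminant <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "reference_illuminant_d65like.csv",
                        package = "alanrisk", mustWork = TRUE)
  read_spectrum_csv(path, name = "reference")
}

#' Read / write a spectrum as 2-column CSV
#'
#' The on-disk interchange format for spectra and sensitivity curves:
#' a header line then `wavelength_nm,value` rows.
#'
#' @param path File path.
#' @param name Optional label for the returned [spd].
#' @return `read_spectrum_csv` returns an [spd]; `write_spectrum_csv`
#'   invisibly returns `path`.
#' @export
read_spectrum_csv <- function(path, name = NULL) {
  tab <- utils::read.csv(path)
  spd(tab[[1]], tab[[2]], name = name)
}

#' @rdname read_spectrum_csv
#' @param x An [spd].
#' @export
write_spectrum_csv <- function(x, path) {
  utils::write.csv(data.frame(wavelength_nm = x$wavelength, value = x$power),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a camera response from CSV
#'
#' Expects 4 columns: `wavelength_nm, r, g, b`.
#'
#' @param path File path.
#' @return A [camera_response].
#' @export
read_camera_csv <- function(path) {
  tab <- utils::read.csv(path)
  camera_response(tab[[1]], r = tab[["r"]], g = tab[["g"]], b = tab[["b"]])
}

# integral of spd power times a weighting curve over their common support
weighted_integral <- function(x, curve_wl, curve_val) {
  lo <- max(min(x$wavelength), min(curve_wl))
  hi <- min(max(x$wavelength), max(curve_wl))
  if (lo >= hi) stop("wavelength supports do not overlap")
  keep <- x$wavelength >= lo & x$wavelength <= hi
  wl <- x$wavelength[keep]
  if (length(wl) < 2L) stop("wavelength supports do not overlap")
  sens <- stats::approx(curve_wl, curve_val, xout = wl, yleft = 0,
                        yright = 0)$y
  pracma::trapz(wl, x$power[keep] * sens)
}

#' Band signal
#'
#' Trapezoidal integral of spectral power times channel sensitivity over the
#' common wavelength grid: the (relative) flux the channel would record.
#'
#' @param x An [spd].
#' @param channel One channel of a [camera_response] (e.g. `camera$g`), or any
#'   list with `wavelength` and `sensitivity` components.
#' @return Nonnegative scalar flux in relative units.
#' @export
band_signal <- function(x, channel) {
  stopifnot(inherits(x, "spd"))
  weighted_integral(x, channel$wavelength, channel$sensitivity)
}

#' Colour ratios of a spectrum under a camera
#'
#' Band-signal ratios B/G, G/R and R/G. A zero denominator yields `NA` for
#' that ratio (it propagates as a masked value downstream).
#'
#' @param x An [spd].
#' @param camera A [camera_response].
#' @return Named numeric vector `c(b_over_g, g_over_r, r_over_g)`.
#' @export
color_ratios <- function(x, camera = default_camera()) {
  b <- band_signal(x, camera$b)
  g <- band_signal(x, camera$g)
  r <- band_signal(x, camera$r)
  if (!all(is.finite(c(b, g, r)))) stop("band signals must be finite")
  c(b_over_g = if (g > 0) b / g else NA_real_,
    g_over_r = if (r > 0) g / r else NA_real_,
    r_over_g = if (g > 0) r / g else NA_real_)
}

#' Spectral index of a spectrum
#'
#' Ratio-of-ratios index: the action-weighted content of the spectrum per unit
#' photopic content, normalised by the same quantity for a reference
#' illuminant, so that `spectral_index(reference) == 1`. With the melatonin
#' suppression action spectrum this is the melatonin suppression index (MSI);
#' with the scotopic/starlight curve, the star light index (SLI).
#'
#' @param x An [spd].
#' @param action An [action_spectrum].
#' @param reference Reference [spd]; default the bundled D65-like illuminant.
#' @param photopic Photopic weighting curve; default the bundled curve.
#' @return Nonnegative scalar; `NA` if the spectrum has zero photopic content.
#' @export
spectral_index <- function(x, action,
                           reference = reference_illuminant(),
                           photopic = action_spectrum("photopic")) {
  num <- weighted_integral(x, action$wavelength, action$weight)
  den <- weighted_integral(x, photopic$wavelength, photopic$weight)
  if (den <= 0) return(NA_real_)
  rnum <- weighted_integral(reference, action$wavelength, action$weight)
  rden <- weighted_integral(reference, photopic$wavelength, photopic$weight)
  (num / den) / (rnum / rden)
}
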
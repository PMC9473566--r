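# ground-truthed synthetic acquisitions: per-pixel lamp mixtures that shift
# from sodium-dominated (epoch 1) to LED-dominated (epoch 2), camera frames
# with the instrumental distortions the calibration chain must undo, and a
# VIIRS-like panchromatic raster for masking and intensity estimation.

#' Acquisition geometry
#'
#' Metadata of one camera acquisition.
#'
#' @param angle_deg Observation angle from nadir, degrees, in `[0, 70]`.
#' @param focal_mm Lens focal length (mm).
#' @param origin_px Grid indices `c(row, col)` of the frame's top-left pixel.
#' @param frame_shape Frame size `c(rows, cols)` in pixels.
#' @param timestamp Acquisition time (decimal year).
#' @param exposure_s Exposure time (s), > 0.
#' @param iso ISO setting, > 0.
#' @param lens_t Per-frame grey transmittance factor (lens/window), in (0, 1].
#' @param frame_id Unique frame identifier string.
#' @return Object of class `acquisition_geometry`.
#' @export
acquisition_geometry <- function(angle_deg, focal_mm, origin_px, frame_shape,
                                 timestamp, exposure_s, iso, lens_t = 1,
                                 frame_id = "frame") {
  stopifnot(angle_deg >= 0, angle_deg <= 70, exposure_s > 0, iso > 0,
            lens_t > 0, lens_t <= 1, focal_mm > 0)
  structure(list(angle_deg = angle_deg, focal_mm = focal_mm,
                 origin_px = as.integer(origin_px),
                 frame_shape = as.integer(frame_shape),
                 timestamp = timestamp, exposure_s = exposure_s, iso = iso,
                 lens_t = lens_t, frame_id = frame_id),
            class = "acquisition_geometry")
}

#' Distortion and instrument configuration for frame rendering
#'
#' Defaults model a DSLR night acquisition: radial vignetting, a
#' linear-then-power sensor response rolling off above a knee at 80% of full
#' well, mild inter-channel crosstalk, per-band atmospheric transmittance
#' (stronger extinction in the blue), occluding clouds, photon + read noise,
#' and georeferencing jitter of 4 pixels RMSE on the control points.
#'
#' @param vignette Radial polynomial coefficients `c(a2, a4)`:
#'   `v(r) = 1 - a2 r^2 - a4 r^4` with `r` the radius normalised to the frame
#'   half-diagonal.
#' @param nonlinearity List: `fullwell` (counts), `knee_frac` (knee as a
#'   fraction of full well) and `power` (< 1; roll-off exponent above the
#'   knee).
#' @param crosstalk 3x3 nonnegative channel mixing matrix (rows R, G, B).
#' @param t_atm Per-band atmospheric transmittance at nadir, named r/g/b.
#' @param cloud_fraction Fraction of frame area covered by cloud.
#' @param cloud_transmittance Fraction of scene radiance passing cloud.
#' @param cloud_glow Faint diffuse cloud radiance added per band
#'   (nW cm-2 sr-1).
#' @param gain Instrumental gain: counts per (nW cm-2 sr-1 s) at `ref_iso`.
#' @param ref_iso Reference ISO for the gain.
#' @param electrons_per_count Conversion used in the photon-noise model;
#'   noise sd in counts is `sqrt(counts / electrons_per_count + read_noise^2)`.
#' @param read_noise Read-noise floor (counts).
#' @param n_stars Reference point sources injected per frame.
#' @param n_control Ground control points per frame.
#' @param georef_rmse_px Control-point jitter, total RMSE in pixels.
#' @param max_airmass Cap on `1 / cos(angle)`.
#' @return A list of class `distortion_config`.
#' @export
distortion_config <- function(vignette = c(0.30, 0.15),
                              nonlinearity = list(fullwell = 16383,
                                                  knee_frac = 0.8,
                                                  power = 0.6),
                              crosstalk = rbind(c(0.94, 0.05, 0.01),
                                                c(0.04, 0.93, 0.03),
                                                c(0.01, 0.06, 0.93)),
                              t_atm = c(r = 0.92, g = 0.88, b = 0.82),
                              cloud_fraction = 0.10,
                              cloud_transmittance = 0.03,
                              cloud_glow = 0.02,
                              gain = 540, ref_iso = 200,
                              electrons_per_count = 4, read_noise = 2,
                              n_stars = 25, n_control = 25,
                              georef_rmse_px = 4, max_airmass = 3) {
  stopifnot(all(crosstalk >= 0), all(t_atm > 0), all(t_atm <= 1),
            nonlinearity$power > 0, nonlinearity$power <= 1,
            cloud_fraction >= 0, cloud_fraction < 1)
  structure(list(vignette = vignette, nonlinearity = nonlinearity,
                 crosstalk = crosstalk, t_atm = t_atm,
                 cloud_fraction = cloud_fraction,
                 cloud_transmittance = cloud_transmittance,
                 cloud_glow = cloud_glow, gain = gain, ref_iso = ref_iso,
                 electrons_per_count = electrons_per_count,
                 read_noise = read_noise, n_stars = n_stars,
                 n_control = n_control, georef_rmse_px = georef_rmse_px,
                 max_airmass = max_airmass),
            class = "distortion_config")
}

#' All-off distortion configuration
#'
#' Identity optics and sensor: no vignetting, linear response, no crosstalk,
#' unit atmosphere, no clouds, no noise, no control-point jitter. Useful for
#' round-trip and unit tests.
#'
#' @inheritParams distortion_config
#' @param ... Overrides passed on to [distortion_config()].
#' @return A `distortion_config`.
#' @export
distortion_config_off <- function(...) {
  args <- list(vignette = c(0, 0),
               nonlinearity = list(fullwell = Inf, knee_frac = 1, power = 1),
               crosstalk = diag(3), t_atm = c(r = 1, g = 1, b = 1),
               cloud_fraction = 0, electrons_per_count = Inf,
               read_noise = 0, georef_rmse_px = 0)
  do.call(distortion_config, utils::modifyList(args, list(...)))
}

# band signals of each lamp class under the camera plus a VIIRS-like
# 480-920 nm boxcar; rows = lamp classes, cols = r, g, b, viirs
class_band_signals <- function(classes, camera, wavelength_nm = 380:780) {
  viirs_chan <- list(wavelength = wavelength_nm,
                     sensitivity = as.numeric(wavelength_nm >= 480 &
                                              wavelength_nm <= 920))
  t(vapply(classes, function(cl) {
    s <- lamp_spd(cl, wavelength_nm)
    c(r = band_signal(s, camera$r), g = band_signal(s, camera$g),
      b = band_signal(s, camera$b), viirs = band_signal(s, viirs_chan))
  }, numeric(4)))
}

#' Synthetic lamp-mixture maps for two epochs
#'
#' Seeded ground truth for the full pipeline: city footprints are
#' Gaussian-decay emission blobs; epoch 1 is sodium-dominated (high-pressure
#' sodium with minority low-pressure sodium, mercury and fluorescent light);
#' epoch 2 is identical except that a random fraction `epoch_shift` of lit
#' pixels has its sodium weight reassigned to white LED (3000/4000 K mix),
#' emulating the LED streetlight conversion.
#'
#' @param n_cities Number of city blobs.
#' @param grid_shape `c(rows, cols)` of the analysis grid.
#' @param epoch_shift Fraction in `[0, 1]` of lit pixels converted to LED in
#'   epoch 2.
#' @param seed Integer seed; the maps are deterministic given it.
#' @param origin,res Grid transform (see [alan_grid()]).
#' @return List of two `lamp_mix_map` objects (`epoch1`, `epoch2`), each with
#'   per-pixel class weights, total emission scale (nW cm-2 sr-1 equivalent),
#'   epoch label and grid georeferencing.
#' @export
make_lamp_maps <- function(n_cities, grid_shape, epoch_shift, seed = 1,
                           origin = c(4e6, 3.5e6), res = 500) {
  stopifnot(epoch_shift >= 0, epoch_shift <= 1, n_cities >= 1)
  nr <- grid_shape[1]; nc <- grid_shape[2]
  if (nr * nc < 400 * n_cities)
    stop("grid too small for ", n_cities, " cities (need >= 400 px each)")
  classes <- lamp_classes()
  K <- length(classes)
  set.seed(seed)
  cr <- stats::runif(n_cities, 0.1 * nr, 0.9 * nr)
  cc <- stats::runif(n_cities, 0.1 * nc, 0.9 * nc)
  peak <- stats::rlnorm(n_cities, log(40), 0.7)
  sig <- stats::runif(n_cities, 5, 11)
  # epoch-1 city mixtures: sodium-dominated with minority white technologies
  w_hps <- stats::runif(n_cities, 0.45, 0.70)
  w_lps <- stats::runif(n_cities, 0.05, 0.20)
  w_mer <- stats::runif(n_cities, 0.05, 0.20)
  w_flu <- pmax(1 - w_hps - w_lps - w_mer, 0)
  citymix <- cbind(lps = w_lps, hps = w_hps, mercury = w_mer,
                   metal_halide = 0, fluorescent = w_flu,
                   led_3000k = 0, led_4000k = 0)
  row <- matrix(seq_len(nr), nr, nc)
  col <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  scale <- matrix(0, nr, nc)
  contrib <- matrix(0, nr * nc, n_cities)
  for (i in seq_len(n_cities)) {
    blob <- peak[i] * exp(-((row - cr[i])^2 + (col - cc[i])^2) /
                            (2 * sig[i]^2))
    scale <- scale + blob
    contrib[, i] <- as.vector(blob)
  }
  lit <- scale >= 0.1
  scale[!lit] <- 0
  share <- contrib / pmax(rowSums(contrib), .Machine$double.eps)
  W <- share %*% citymix                      # npix x K mixture weights
  W[!as.vector(lit), ] <- 0
  map1 <- structure(list(weights = array(W, c(nr, nc, K)), classes = classes,
                         scale = scale, epoch = "epoch1", crs = "EPSG:3035",
                         origin = origin, res = res),
                    class = "lamp_mix_map")
  # epoch 2: seeded conversion of sodium weight to LED in a subset of pixels
  set.seed(seed + 1L)
  W2 <- W
  lit_idx <- which(as.vector(lit))
  if (epoch_shift > 0 && length(lit_idx) > 0) {
    conv <- lit_idx[stats::runif(length(lit_idx)) < epoch_shift]
    if (epoch_shift >= 1) conv <- lit_idx
    sodium <- W2[conv, "lps"] + W2[conv, "hps"]
    f3000 <- stats::runif(length(conv), 0.3, 0.7)
    W2[conv, "lps"] <- 0
    W2[conv, "hps"] <- 0
    W2[conv, "led_3000k"] <- W2[conv, "led_3000k"] + sodium * f3000
    W2[conv, "led_4000k"] <- W2[conv, "led_4000k"] + sodium * (1 - f3000)
  }
  map2 <- structure(list(weights = array(W2, c(nr, nc, K)), classes = classes,
                         scale = scale, epoch = "epoch2", crs = "EPSG:3035",
                         origin = origin, res = res),
                    class = "lamp_mix_map")
  list(epoch1 = map1, epoch2 = map2)
}

#' @export
print.lamp_mix_map <- function(x, ...) {
  cat(sprintf("<lamp_mix_map %s: %dx%d px, %d lit>\n", x$epoch,
              nrow(x$scale), ncol(x$scale), sum(x$scale > 0)))
  invisible(x)
}

#' Ground-truth band radiance of a lamp-mixture map
#'
#' Per-pixel R, G, B radiance implied by the mixture weights and emission
#' scale under a camera: the quantity the calibration + mosaic pipeline is
#' supposed to recover.
#'
#' @param map A `lamp_mix_map`.
#' @param camera A [camera_response].
#' @return An [alan_grid] with layers `r`, `g`, `b`; unlit pixels masked.
#' @export
truth_radiance <- function(map, camera = default_camera()) {
  s <- class_band_signals(map$classes, camera)
  d <- dim(map$scale)
  W <- matrix(map$weights, prod(d), length(map$classes))
  layers <- lapply(c("r", "g", "b"), function(bnd)
    matrix(as.vector(map$scale) * (W %*% s[, bnd]), d[1], d[2]))
  names(layers) <- c("r", "g", "b")
  mask <- matrix(0L, d[1], d[2])
  mask[map$scale <= 0] <- mask_codes()[["unlit"]]
  alan_grid(layers, crs = map$crs, origin = map$origin, res = map$res,
            mask = mask)
}

#' VIIRS-like panchromatic raster of a lamp-mixture map
#'
#' Integrates each pixel's mixture spectrum against a 480-920 nm boxcar
#' sensitivity (the day/night band passband), in nW cm-2 sr-1. The band is
#' blind below 480 nm, so blue-only emission contributes nothing.
#'
#' @param map A `lamp_mix_map`.
#' @param camera A [camera_response] (used only for its wavelength grid).
#' @return Single-layer [alan_grid] `viirs`.
#' @export
render_viirs <- function(map, camera = default_camera()) {
  s <- class_band_signals(map$classes, camera)
  d <- dim(map$scale)
  W <- matrix(map$weights, prod(d), length(map$classes))
  v <- matrix(as.vector(map$scale) * (W %*% s[, "viirs"]), d[1], d[2])
  alan_grid(list(viirs = v), crs = map$crs, origin = map$origin,
            res = map$res)
}

# separable moving-average blur (used for the synthetic cloud field)
blur_matrix <- function(m, k) {
  kern <- rep(1 / k, k)
  m <- apply(m, 2, function(v) stats::filter(v, kern, circular = TRUE))
  t(apply(t(m), 2, function(v) stats::filter(v, kern, circular = TRUE)))
}

# radial vignette raster for a frame shape (r normalised to half-diagonal)
vignette_raster <- function(shape, coefs) {
  nr <- shape[1]; nc <- shape[2]
  rowc <- (nr + 1) / 2; colc <- (nc + 1) / 2
  r2 <- (outer(seq_len(nr) - rowc, rep(1, nc))^2 +
         outer(rep(1, nr), seq_len(nc) - colc)^2) /
        ((nr - rowc)^2 + (nc - colc)^2)
  1 - coefs[1] * r2 - coefs[2] * r2^2
}

# sensor response: linear below the knee, power roll-off above
apply_nonlinearity <- function(counts, nl) {
  knee <- nl$knee_frac * nl$fullwell
  if (!is.finite(knee) || nl$power == 1) return(counts)
  hi <- counts > knee
  counts[hi] <- knee * (counts[hi] / knee)^nl$power
  counts
}

#' Render a synthetic camera frame
#'
#' Forward model of one acquisition over a window of the scene: ground-truth
#' band radiance is scaled by exposure, ISO gain, lens transmittance and
#' per-band atmospheric transmittance raised to the airmass; clouds occlude
#' the scene (strong attenuation plus a faint diffuse glow); reference point
#' sources ("stars") are injected with known radiances (no atmospheric
#' extinction: calibration sources sit above the atmosphere); channel
#' crosstalk, vignetting, photon/read noise and the nonlinear sensor response
#' are then applied. All ground truth needed by tests (radiance, cloud mask,
#' star table, vignette, true frame-to-grid offset) rides along in `$truth`.
#'
#' @param map A `lamp_mix_map`.
#' @param camera A [camera_response].
#' @param geom An [acquisition_geometry]; its `origin_px`/`frame_shape` select
#'   the scene window (must lie inside the grid).
#' @param distortions A [distortion_config()].
#' @param seed Integer seed; frames are bit-identical given identical seeds.
#' @param cloud_seed Optional separate seed for the cloud field (defaults to
#'   `seed`). Passing the same `cloud_seed` for corresponding frames of two
#'   epochs gives both epochs a common cloud realisation, so that epoch
#'   contrasts are not confounded by differential coverage.
#' @return Object of class `raw_frame`: `counts` (rows x cols x 3, band order
#'   R, G, B), `geometry`, `cps` (control points: frame and map pixel
#'   coordinates), `truth`, `distortions`.
#' @export
render_frame <- function(map, camera, geom, distortions = distortion_config(),
                         seed = 1, cloud_seed = seed) {
  d <- distortions
  nr <- geom$frame_shape[1]; nc <- geom$frame_shape[2]
  r0 <- geom$origin_px[1]; c0 <- geom$origin_px[2]
  if (r0 < 1 || c0 < 1 || r0 + nr - 1 > nrow(map$scale) ||
      c0 + nc - 1 > ncol(map$scale))
    stop("frame window falls outside the scene grid")
  rows <- r0:(r0 + nr - 1); cols <- c0:(c0 + nc - 1)
  s <- class_band_signals(map$classes, camera)
  W <- matrix(map$weights[rows, cols, ], nr * nc, length(map$classes))
  scale <- as.vector(map$scale[rows, cols])
  L <- vapply(c("r", "g", "b"), function(bnd)
    scale * (W %*% s[, bnd])[, 1], numeric(nr * nc))
  truth_L <- array(L, c(nr, nc, 3))
  # clouds occlude the ground scene
  cloud <- matrix(FALSE, nr, nc)
  if (d$cloud_fraction > 0) {
    set.seed(cloud_seed)
    field <- blur_matrix(matrix(stats::rnorm(nr * nc), nr, nc),
                         max(3, round(min(nr, nc) / 8)))
    cloud <- field >= stats::quantile(field, 1 - d$cloud_fraction)
    ci <- as.vector(cloud)
    L[ci, ] <- L[ci, ] * d$cloud_transmittance + d$cloud_glow
  }
  set.seed(seed)
  airmass <- min(1 / cos(geom$angle_deg * pi / 180), d$max_airmass)
  settings <- d$gain * geom$exposure_s * (geom$iso / d$ref_iso) * geom$lens_t
  counts <- L * rep(settings * d$t_atm[c("r", "g", "b")]^airmass,
                    each = nr * nc)
  # reference point sources: known radiance, no atmospheric extinction.
  # Placed over dark sky (no lit scene pixel within the photometry annulus),
  # as in calibration frames of star fields.
  stars <- NULL
  if (d$n_stars > 0) {
    # progressively relax the darkness requirement if the window is bright;
    # within each level, greedy selection with a minimum separation so
    # photometry apertures never overlap
    pick <- NULL
    for (dark_max in c(0.5, 2, 8, 32, Inf)) {
      lit_near <- blur_matrix(matrix(as.numeric(scale >= dark_max), nr, nc),
                              15)
      cand <- which(lit_near < 1e-9, arr.ind = TRUE)
      cand <- cand[cand[, 1] >= 8 & cand[, 1] <= nr - 7 &
                   cand[, 2] >= 8 & cand[, 2] <= nc - 7, , drop = FALSE]
      if (nrow(cand) < 3L) next
      cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
      pick <- cand[1, , drop = FALSE]
      for (j in seq_len(nrow(cand))) {
        if (nrow(pick) >= d$n_stars) break
        dmin <- min(sqrt((pick[, 1] - cand[j, 1])^2 +
                         (pick[, 2] - cand[j, 2])^2))
        if (dmin >= 12) pick <- rbind(pick, cand[j, ])
      }
      if (nrow(pick) >= 3L) break
    }
    if (is.null(pick) || nrow(pick) < 3L)
      stop("frame window has too little dark sky for reference sources")
    n_star <- nrow(pick)
    sr <- pick[, 1]; sc <- pick[, 2]
    srad <- matrix(stats::rlnorm(3 * n_star, log(8), 0.4), n_star, 3)
    colnames(srad) <- c("r", "g", "b")
    stars <- data.frame(row = sr, col = sc, srad)
    psf <- rbind(c(0.02, 0.08, 0.02), c(0.08, 0.60, 0.08),
                 c(0.02, 0.08, 0.02))
    for (i in seq_len(n_star)) {
      for (b in 1:3) {
        idx <- cbind(rep(sr[i] + (-1:1), 3), rep(sc[i] + (-1:1), each = 3))
        flat <- (idx[, 2] - 1) * nr + idx[, 1]
        counts[flat, b] <- counts[flat, b] +
          srad[i, b] * settings * as.vector(t(psf))
      }
    }
  }
  counts <- counts %*% t(d$crosstalk)           # channel crosstalk
  vig <- vignette_raster(c(nr, nc), d$vignette)
  counts <- counts * as.vector(vig)
  if (is.finite(d$electrons_per_count) || d$read_noise > 0) {
    sd <- sqrt(pmax(counts, 0) / d$electrons_per_count + d$read_noise^2)
    counts <- counts + stats::rnorm(length(counts)) * sd
  }
  counts <- pmax(counts, 0)
  counts <- apply_nonlinearity(counts, d$nonlinearity)
  # ground control points: true frame-to-grid correspondence plus jitter
  n_cp <- d$n_control
  cp_fr <- stats::runif(n_cp, 1, nr)
  cp_fc <- stats::runif(n_cp, 1, nc)
  jit <- d$georef_rmse_px / sqrt(2)
  cps <- data.frame(frame_row = cp_fr, frame_col = cp_fc,
                    map_row = cp_fr + (r0 - 1) + stats::rnorm(n_cp, 0, jit),
                    map_col = cp_fc + (c0 - 1) + stats::rnorm(n_cp, 0, jit))
  structure(list(counts = array(counts, c(nr, nc, 3)), geometry = geom,
                 cps = cps,
                 truth = list(radiance = truth_L, cloud = cloud,
                              stars = stars, vignette = vig,
                              origin_px = c(r0, c0), airmass = airmass,
                              settings = settings),
                 distortions = d),
            class = "raw_frame")
}

#' @export
print.raw_frame <- function(x, ...) {
  cat(sprintf(
    "<raw_frame %s: %dx%d px, angle %.1f deg, %g s, ISO %g, %g mm>\n",
    x$geometry$frame_id, dim(x$counts)[1], dim(x$counts)[2],
    x$geometry$angle_deg, x$geometry$exposure_s, x$geometry$iso,
    x$geometry$focal_mm))
  invisible(x)
}

# Sutherland-Hodgman clip of a convex polygon by half-plane a.x <= b
clip_halfplane <- function(poly, a, b) {
  n <- nrow(poly)
  out <- matrix(NA_real_, 0, 2)
  for (i in seq_len(n)) {
    p <- poly[i, ]; q <- poly[if (i == n) 1 else i + 1, ]
    pin <- sum(a * p) <= b; qin <- sum(a * q) <= b
    if (pin) out <- rbind(out, p)
    if (xor(pin, qin)) {
      t <- (b - sum(a * p)) / sum(a * (q - p))
      out <- rbind(out, p + t * (q - p))
    }
  }
  out
}

#' Synthetic region polygons
#'
#' Partition mode produces a seeded Voronoi partition of the grid extent into
#' named convex polygons (stand-ins for country boundaries); ranges mode
#' produces possibly overlapping random ellipses (stand-ins for species
#' ranges; the study covers 38 bat species).
#'
#' @param n_regions Number of regions (>= 1).
#' @param grid An [alan_grid] defining extent and CRS.
#' @param seed Integer seed.
#' @param mode `"partition"` or `"ranges"`.
#' @return A [region_set].
#' @export
make_regions <- function(n_regions, grid, seed = 1,
                         mode = c("partition", "ranges")) {
  stopifnot(n_regions >= 1)
  mode <- match.arg(mode)
  d <- dim(grid)
  x0 <- grid$origin[1]; y1 <- grid$origin[2]
  x1 <- x0 + d[2] * grid$res; y0 <- y1 - d[1] * grid$res
  set.seed(seed)
  if (mode == "partition") {
    if (n_regions == 1) {
      poly <- rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0))
      return(region_set("region_01", list(poly), crs = grid$crs,
                        mode = mode))
    }
    seeds <- cbind(stats::runif(n_regions, x0, x1),
                   stats::runif(n_regions, y0, y1))
    bbox <- rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))
    polys <- lapply(seq_len(n_regions), function(i) {
      poly <- bbox
      for (j in seq_len(n_regions)) {
        if (j == i) next
        a <- seeds[j, ] - seeds[i, ]
        b <- sum(a * (seeds[i, ] + seeds[j, ]) / 2)
        poly <- clip_halfplane(poly, a, b)
        if (nrow(poly) < 3) break
      }
      poly
    })
    keep <- vapply(polys, function(p) nrow(p) >= 3, logical(1))
    region_set(sprintf("region_%02d", which(keep)), polys[keep],
               crs = grid$crs, mode = mode)
  } else {
    th <- seq(0, 2 * pi, length.out = 65)
    polys <- lapply(seq_len(n_regions), function(i) {
      cx <- stats::runif(1, x0 + 0.15 * (x1 - x0), x1 - 0.15 * (x1 - x0))
      cy <- stats::runif(1, y0 + 0.15 * (y1 - y0), y1 - 0.15 * (y1 - y0))
      ax <- stats::runif(1, 0.08, 0.30) * (x1 - x0)
      ay <- stats::runif(1, 0.08, 0.30) * (y1 - y0)
      rot <- stats::runif(1, 0, pi)
      ex <- ax * cos(th); ey <- ay * sin(th)
      cbind(cx + ex * cos(rot) - ey * sin(rot),
            cy + ex * sin(rot) + ey * cos(rot))
    })
    region_set(sprintf("species_%02d", seq_len(n_regions)), polys,
               crs = grid$crs, mode = mode)
  }
}
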
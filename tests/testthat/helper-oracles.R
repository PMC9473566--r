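# shared oracles and fixture builders (all fixtures generated in code)

# brute-force Kruskal-Wallis with midrank ties: explicit ranking, tie-corrected
kw_oracle <- function(a, b) {
  x <- c(a, b)
  g <- rep(1:2, c(length(a), length(b)))
  r <- rank(x)
  N <- length(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (N + 1) / 2)^2))
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr <= 0) return(NaN)
  H / corr
}

# boxcar sensitivity channel on a wavelength grid (half-open [lo, hi) so a
# width-w boxcar integrates to exactly w under the trapezoid rule)
boxcar_channel <- function(wl, lo, hi) {
  list(wavelength = wl, sensitivity = as.numeric(wl >= lo & wl < hi))
}

# single-class lamp map: a flat lit square with an unlit border (dark sky
# for the reference sources)
make_pure_map <- function(class, shape = c(72, 72), scale_value = 20,
                          border = 16) {
  classes <- lamp_classes()
  W <- array(0, c(shape, length(classes)))
  lit <- matrix(FALSE, shape[1], shape[2])
  lit[(border + 1):(shape[1] - border), (border + 1):(shape[2] - border)] <- TRUE
  Wk <- matrix(0, shape[1], shape[2])
  Wk[lit] <- 1
  W[, , which(classes == class)] <- Wk
  scale <- matrix(0, shape[1], shape[2])
  scale[lit] <- scale_value
  structure(list(weights = W, classes = classes, scale = scale,
                 epoch = "epoch1", crs = "EPSG:3035",
                 origin = c(4e6, 3.5e6), res = 500),
            class = "lamp_mix_map")
}

# minimal radiance_frame for georeference tests
make_radiance_frame <- function(radiance, cps, angle = 0, frame_id = "f") {
  geom <- acquisition_geometry(angle_deg = angle, focal_mm = 180,
                               origin_px = c(1, 1),
                               frame_shape = dim(radiance)[1:2],
                               timestamp = 2012.5, exposure_s = 0.25,
                               iso = 800, lens_t = 1, frame_id = frame_id)
  structure(list(radiance = radiance,
                 mask = matrix(0L, dim(radiance)[1], dim(radiance)[2]),
                 geometry = geom, cps = cps, truth = NULL),
            class = "radiance_frame")
}

# ratio grid with constant, mutually consistent ratio values
make_ratio_grid <- function(nr = 40, nc = 40, bg = 0.5, gr = 0.5) {
  alan_grid(list(b_over_g = matrix(bg, nr, nc),
                 g_over_r = matrix(gr, nr, nc),
                 r_over_g = matrix(1 / gr, nr, nc)),
            origin = c(0, nr * 500), res = 500)
}
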
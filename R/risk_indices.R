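# VIIRS-corrected band intensities and biological index grids.
# The intensity models convert a panchromatic VIIRS radiance and a colour
# ratio into an estimated band intensity: G and P (phototaxis-weighted) use
# exponential models in G/R, B uses a quadratic in B/G.

#' Published intensity-model coefficients
#'
#' Point estimates and bootstrap 95% confidence intervals of the three
#' VIIRS-correction models: `G/VIIRS = a * b^(G/R)` with a = 0.21
#' (+0.21/-0.06) and b = 1.5 (+0.09/-0.30); `B/VIIRS = c0 + c1 x + c2 x^2` in
#' x = B/G with c0 = -0.03 (+0.03/-0.04), c1 = 0.6 (+/-0.20), c2 = 1.3
#' (+0.20/-0.30); and `P/VIIRS = p0 * p1^(G/R)` with p0 = 0.23 (+0.05/-0.03)
#' and p1 = 0.21 (+0.06/-0.21).
#'
#' @return Nested list; each parameter is `c(lower, point, upper)`.
#' @export
default_coefficients <- function() {
  list(g_over_viirs = list(a = c(0.15, 0.21, 0.42),
                           b = c(1.20, 1.50, 1.59)),
       b_over_viirs = list(c0 = c(-0.07, -0.03, 0.00),
                           c1 = c(0.40, 0.60, 0.80),
                           c2 = c(1.00, 1.30, 1.50)),
       p_over_viirs = list(p0 = c(0.20, 0.23, 0.28),
                           p1 = c(0.00, 0.21, 0.27)))
}

check_coeffs <- function(coeffs) {
  for (m in names(coeffs)) for (p in names(coeffs[[m]])) {
    v <- coeffs[[m]][[p]]
    if (length(v) != 3 || v[1] > v[2] || v[2] > v[3])
      stop("coefficient ", m, "$", p, " must be c(lower, point, upper)")
  }
  invisible(coeffs)
}

#' Write / read intensity-model coefficients as JSON
#'
#' @param coeffs Coefficient list as from [default_coefficients()].
#' @param path File path.
#' @return `write_coefficients` invisibly returns `path`;
#'   `read_coefficients` returns the validated list.
#' @export
write_coefficients <- function(coeffs, path) {
  jsonlite::write_json(check_coeffs(coeffs), path, digits = NA)
  invisible(path)
}

#' @rdname write_coefficients
#' @export
read_coefficients <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_coeffs(lapply(obj, function(m) lapply(m, as.numeric)))
}

pt <- function(x) x[2]

#' G-band intensity per unit VIIRS radiance
#'
#' `a * b^(G/R)`: the fraction of VIIRS panchromatic radiance attributable to
#' the camera G band, as a function of the G/R colour ratio. Increasing in
#' G/R (whiter light carries more G per unit VIIRS).
#'
#' @param g_over_r Nonnegative scalar, vector or matrix of G/R ratios.
#' @param coeffs Coefficients (see [default_coefficients()]).
#' @return Same shape as `g_over_r`.
#' @export
g_over_viirs <- function(g_over_r, coeffs = default_coefficients()) {
  if (any(g_over_r < 0, na.rm = TRUE)) stop("G/R ratios must be nonnegative")
  k <- coeffs$g_over_viirs
  pt(k$a) * pt(k$b)^g_over_r
}

#' B-band intensity per unit VIIRS radiance
#'
#' `c0 + c1 x + c2 x^2` in x = B/G. The raw quadratic is slightly negative at
#' B/G = 0 (c0 = -0.03); negative values are clamped to 0 by default (counted
#' in attribute `n_clamped`) since negative radiance is unphysical.
#'
#' @param b_over_g Nonnegative scalar, vector or matrix of B/G ratios.
#' @param coeffs Coefficients.
#' @param clamp Clamp negative outputs to 0 (default `TRUE`).
#' @return Same shape as `b_over_g`, attribute `n_clamped` when clamping.
#' @export
b_over_viirs <- function(b_over_g, coeffs = default_coefficients(),
                         clamp = TRUE) {
  k <- coeffs$b_over_viirs
  v <- pt(k$c0) + pt(k$c1) * b_over_g + pt(k$c2) * b_over_g^2
  if (clamp) {
    n <- sum(v < 0, na.rm = TRUE)
    v[!is.na(v) & v < 0] <- 0
    attr(v, "n_clamped") <- n
  }
  v
}

#' Phototaxis-weighted intensity per unit VIIRS radiance
#'
#' `p0 * p1^(G/R)` with p1 = 0.21 < 1: decreasing in G/R, i.e. redder light
#' carries a larger phototaxic fraction of the VIIRS radiance under this
#' model's normalisation.
#'
#' @inheritParams g_over_viirs
#' @return Same shape as `g_over_r`.
#' @export
p_over_viirs <- function(g_over_r, coeffs = default_coefficients()) {
  if (any(g_over_r < 0, na.rm = TRUE)) stop("G/R ratios must be nonnegative")
  k <- coeffs$p_over_viirs
  pt(k$p0) * pt(k$p1)^g_over_r
}

#' Estimate a band-intensity grid from VIIRS and colour ratios
#'
#' Per-pixel VIIRS radiance times the corresponding ratio-model output:
#' `which = "G"` uses [g_over_viirs()] on G/R, `"B"` uses [b_over_viirs()] on
#' B/G, `"P"` uses [p_over_viirs()] on G/R. Homogeneous in VIIRS by
#' construction. The output mask is the union of the inputs' masks.
#'
#' @param viirs An [alan_grid] with layer `viirs`.
#' @param rg A co-registered ratio grid ([compute_ratios()]).
#' @param which `"G"`, `"B"` or `"P"`.
#' @param coeffs Coefficients.
#' @return Single-layer [alan_grid] (nW cm-2 sr-1).
#' @export
estimate_intensity <- function(viirs, rg, which = c("G", "B", "P"),
                               coeffs = default_coefficients()) {
  which <- match.arg(which)
  check_congruent(viirs, rg)
  mask <- rg$mask
  mask[mask == 0L & viirs$mask != 0L] <- viirs$mask[mask == 0L & viirs$mask != 0L]
  ok <- mask == 0L
  ratio <- rg$layers[[if (which == "B") "b_over_g" else "g_over_r"]]
  out <- matrix(NA_real_, nrow(mask), ncol(mask))
  f <- switch(which, G = g_over_viirs, B = b_over_viirs, P = p_over_viirs)
  out[ok] <- viirs$layers$viirs[ok] * as.numeric(f(ratio[ok], coeffs))
  layers <- list(out)
  names(layers) <- paste0(tolower(which), "_intensity")
  alan_grid(layers, crs = rg$crs, origin = rg$origin, res = rg$res,
            mask = mask)
}

#' Propagate coefficient confidence intervals through an intensity model
#'
#' Evaluates the model at every corner combination of the coefficients'
#' 95% bounds and returns the pointwise envelope (min/max over corners)
#' alongside the point estimate, so `low <= point <= high` everywhere.
#'
#' @param model `"g_over_viirs"`, `"b_over_viirs"` or `"p_over_viirs"`.
#' @param x Ratio values (scalar, vector or matrix).
#' @param coeffs Coefficients.
#' @return List with `low`, `point`, `high` of the same shape as `x`.
#' @export
propagate_ci <- function(model = c("g_over_viirs", "b_over_viirs",
                                   "p_over_viirs"),
                         x, coeffs = default_coefficients()) {
  model <- match.arg(model)
  k <- coeffs[[model]]
  evalf <- switch(model,
    g_over_viirs = function(p, x) p[1] * p[2]^x,
    b_over_viirs = function(p, x) p[1] + p[2] * x + p[3] * x^2,
    p_over_viirs = function(p, x) p[1] * p[2]^x)
  corners <- unname(as.matrix(expand.grid(lapply(k, function(v) v[c(1, 3)]))))
  lo <- hi <- NULL
  for (i in seq_len(nrow(corners))) {
    v <- unname(evalf(corners[i, ], x))
    lo <- if (is.null(lo)) v else pmin(lo, v)
    hi <- if (is.null(hi)) v else pmax(hi, v)
  }
  point <- unname(evalf(vapply(k, pt, numeric(1)), x))
  list(low = pmin(lo, point), point = point, high = pmax(hi, point))
}

#' Map a ratio grid to a biological index grid
#'
#' Applies a fitted [fit_ratio_index_curve()] model to the grid's matching
#' ratio band, clamping to the model's valid index range. Pixels whose ratio
#' lies outside the model's fitted domain get a value anyway but are flagged
#' in the `extrapolated` attribute.
#'
#' @param rg A ratio grid.
#' @param model A `ratio_index_model`.
#' @return Single-layer [alan_grid] named after the model response, with a
#'   logical `extrapolated` attribute matrix.
#' @export
index_grid <- function(rg, model) {
  band <- model$predictor
  if (!band %in% names(rg$layers))
    stop("ratio grid has no band matching the model predictor: ", band)
  ratio <- rg$layers[[band]]
  ok <- rg$mask == 0L
  out <- matrix(NA_real_, nrow(ratio), ncol(ratio))
  extra <- matrix(FALSE, nrow(ratio), ncol(ratio))
  p <- predict(model, ratio[ok])
  out[ok] <- as.numeric(p)
  extra[ok] <- attr(p, "extrapolated")
  layers <- list(out)
  names(layers) <- model$response
  g <- alan_grid(layers, crs = rg$crs, origin = rg$origin, res = rg$res,
                 mask = rg$mask)
  attr(g, "extrapolated") <- extra
  g
}
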
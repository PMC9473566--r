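# least-squares fits of index-on-ratio curves with bootstrap CIs.
# Two families mirror the functional forms used for the VIIRS-corrected
# intensity models: quadratic in the ratio, and exponential a * b^ratio.

fit_quadratic <- function(x, y) {
  X <- cbind(1, x, x^2)
  q <- qr(X)
  if (q$rank < 3L)
    stop("rank-deficient design: ratios do not span a quadratic fit")
  as.numeric(qr.coef(q, y))
}

# Gauss-Newton fit of y ~ a * b^x, initialised from a log-linear fit
fit_exponential <- function(x, y, max_iter = 100, tol = 1e-12) {
  if (length(unique(round(x, 12))) < 2L)
    stop("rank-deficient design: ratios do not span an exponential fit")
  pos <- y > max(abs(y)) * 1e-9
  if (sum(pos) < 2L) return(c(0, 1))   # all-zero response: flat curve at 0
  init <- stats::lm.fit(cbind(1, x[pos]), log(y[pos]))$coefficients
  a <- exp(init[1]); b <- exp(init[2])
  for (i in seq_len(max_iter)) {
    f <- a * b^x
    r <- y - f
    J <- cbind(b^x, a * x * b^(x - 1))
    step <- tryCatch(qr.solve(crossprod(J) + diag(1e-12, 2), crossprod(J, r)),
                     error = function(e) c(0, 0))
    a <- a + step[1]; b <- max(b + step[2], 1e-8)
    if (sqrt(sum(step^2)) < tol * (abs(a) + abs(b) + tol)) break
  }
  c(a, b)
}

fit_family <- function(x, y, family) {
  switch(family,
         quadratic = fit_quadratic(x, y),
         exponential = fit_exponential(x, y),
         stop("unknown family: ", family))
}

eval_family <- function(coefs, x, family) {
  switch(family,
         quadratic = coefs[1] + coefs[2] * x + coefs[3] * x^2,
         exponential = coefs[1] * coefs[2]^x)
}

#' Fit a colour-ratio to index relationship
#'
#' Least-squares fit of a biological/visual spectral index on a camera colour
#' ratio over a lamp-spectrum library, the "established relationship" used to
#' map ratio grids to index grids. Coefficient 95% confidence intervals come
#' from nonparametric bootstrap resampling of library members (percentile
#' intervals).
#'
#' Family defaults follow the predictor: quadratic in the ratio for B/G
#' predictors and exponential `a * b^ratio` for G/R predictors, mirroring the
#' functional forms of the VIIRS-corrected intensity models.
#'
#' @param library List of [spd] objects (>= number of parameters; a realistic
#'   library spans sodium, mercury, metal-halide, fluorescent and LED classes
#'   plus mixtures, see [lamp_library()]).
#' @param predictor `"b_over_g"` or `"g_over_r"`.
#' @param response `"msi"`, `"sli"` or `"phototaxis"`.
#' @param family `"quadratic"` or `"exponential"`; default chosen from the
#'   predictor.
#' @param camera A [camera_response].
#' @param n_boot Bootstrap replicates for the coefficient CIs (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return An object of class `ratio_index_model` with components
#'   `coefficients`, `ci` (2 x p matrix of percentile bounds), `rmse`,
#'   `family`, `predictor`, `response`, `domain` (fitted ratio range) and
#'   `clamp` (valid index range used by [predict.ratio_index_model()]).
#' @export
fit_ratio_index_curve <- function(library,
                                  predictor = c("b_over_g", "g_over_r"),
                                  response = c("msi", "sli", "phototaxis"),
                                  family = NULL,
                                  camera = default_camera(),
                                  n_boot = 1000, seed = 1) {
  predictor <- match.arg(predictor)
  response <- match.arg(response)
  action <- action_spectrum(switch(response,
                                   msi = "melatonin_suppression",
                                   sli = "scotopic_starlight",
                                   phototaxis = "phototaxis"))
  reference <- reference_illuminant()
  photopic <- action_spectrum("photopic")
  x <- vapply(library, function(s) color_ratios(s, camera)[[predictor]],
              numeric(1))
  y <- vapply(library, function(s)
    spectral_index(s, action, reference, photopic), numeric(1))
  ok <- is.finite(x) & is.finite(y)
  fit_ratio_curve(x[ok], y[ok], family = family, predictor = predictor,
                  response = response, n_boot = n_boot, seed = seed)
}

#' Fit a ratio-index curve from precomputed (ratio, index) pairs
#'
#' Workhorse behind [fit_ratio_index_curve()], exposed for fitting against
#' externally supplied data.
#'
#' @param x Ratio values. @param y Index values.
#' @inheritParams fit_ratio_index_curve
#' @return A `ratio_index_model`.
#' @export
fit_ratio_curve <- function(x, y, family = NULL,
                            predictor = "ratio", response = "index",
                            n_boot = 1000, seed = 1) {
  if (is.null(family))
    family <- if (identical(predictor, "g_over_r")) "exponential" else "quadratic"
  family <- match.arg(family, c("quadratic", "exponential"))
  n_par <- if (family == "quadratic") 3L else 2L
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) <= n_par)
    stop("need more spectra than model parameters (", n_par, ")")
  if (stats::sd(x) < 1e-12)
    stop("rank-deficient design: all predictor ratios identical")
  coefs <- fit_family(x, y, family)
  resid <- y - eval_family(coefs, x, family)
  rmse <- sqrt(mean(resid^2))
  set.seed(seed)
  boots <- matrix(NA_real_, n_boot, n_par)
  n <- length(x)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    boots[b, ] <- tryCatch(fit_family(x[idx], y[idx], family),
                           error = function(e) rep(NA_real_, n_par))
  }
  ci <- apply(boots, 2, stats::quantile, probs = c(0.025, 0.975),
              na.rm = TRUE)
  # percentile bootstrap intervals need not bracket the full-sample point
  # estimate in pathological resamples; widen minimally so they always do
  ci[1, ] <- pmin(ci[1, ], coefs)
  ci[2, ] <- pmax(ci[2, ], coefs)
  names(coefs) <- colnames(ci) <-
    if (family == "quadratic") c("c0", "c1", "c2") else c("a", "b")
  structure(list(coefficients = coefs, ci = ci, rmse = rmse, family = family,
                 predictor = predictor, response = response,
                 domain = range(x), n = n,
                 clamp = if (response %in% c("msi", "sli")) c(0, 1)
                         else c(0, Inf)),
            class = "ratio_index_model")
}

#' @export
print.ratio_index_model <- function(x, ...) {
  cat(sprintf("<ratio_index_model: %s ~ %s (%s), n = %d>\n",
              x$response, x$predictor, x$family, x$n))
  tab <- rbind(estimate = x$coefficients, x$ci)
  print(round(tab, 5))
  cat(sprintf("residual RMSE %.5g over ratio domain [%.3g, %.3g]\n",
              x$rmse, x$domain[1], x$domain[2]))
  invisible(x)
}

#' @export
coef.ratio_index_model <- function(object, ...) object$coefficients

#' Predict an index from ratio values
#'
#' @param object A `ratio_index_model`.
#' @param newdata Numeric vector (or matrix) of ratio values.
#' @param clamp Clamp predictions to the model's valid index range
#'   (default `TRUE`; `[0, 1]` for MSI/SLI).
#' @param ... Unused.
#' @return Predictions with attribute `extrapolated`: logical, `TRUE` where
#'   the ratio lies outside the fitted domain.
#' @export
predict.ratio_index_model <- function(object, newdata, clamp = TRUE, ...) {
  p <- eval_family(object$coefficients, newdata, object$family)
  if (clamp) p <- pmin(pmax(p, object$clamp[1]), object$clamp[2])
  extra <- newdata < object$domain[1] | newdata > object$domain[2]
  if (is.matrix(newdata)) { p <- matrix(p, nrow(newdata)); extra <- matrix(extra, nrow(newdata)) }
  attr(p, "extrapolated") <- extra
  p
}

#' Serialise / restore a ratio-index model as JSON
#'
#' @param object A `ratio_index_model`.
#' @param path File path.
#' @return `write_ratio_index_model` invisibly returns `path`;
#'   `read_ratio_index_model` returns the model.
#' @export
write_ratio_index_model <- function(object, path) {
  obj <- unclass(object)
  obj$ci <- list(lower = unname(obj$ci[1, ]), upper = unname(obj$ci[2, ]))
  obj$coefficients <- as.list(obj$coefficients)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ratio_index_model
#' @export
read_ratio_index_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  coefs <- unlist(obj$coefficients)
  ci <- rbind(`2.5%` = obj$ci$lower, `97.5%` = obj$ci$upper)
  colnames(ci) <- names(coefs)
  structure(list(coefficients = coefs, ci = ci, rmse = obj$rmse,
                 family = obj$family, predictor = obj$predictor,
                 response = obj$response, domain = obj$domain, n = obj$n,
                 clamp = obj$clamp),
            class = "ratio_index_model")
}
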
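#' Lamp classes in the modelled spectrum library
#'
#' @return Character vector of lamp class names.
#' @export
lamp_classes <- function() {
  c("lps", "hps", "mercury", "metal_halide", "fluorescent",
    "led_3000k", "led_4000k")
}

# sum-of-Gaussians line/continuum builder on a 1-nm grid
lamp_curve <- function(wl, mu, amp, sigma) {
  p <- rep(0, length(wl))
  for (i in seq_along(mu))
    p <- p + amp[i] * exp(-(wl - mu[i])^2 / (2 * sigma[i]^2))
  p
}

#' Modelled lamp spectrum
#'
#' Analytic stand-ins for the common street-lighting spectra: line lists for
#' low/high-pressure sodium and mercury vapour, Gaussian-mixture continua for
#' fluorescent and metal halide, and a two-lobe blue-peak-plus-phosphor model
#' for white LEDs at 3000 K and 4000 K correlated colour temperature. Each
#' spectrum is normalised to unit total power so mixture weights are power
#' fractions.
#'
#' @param class One of [lamp_classes()].
#' @param wavelength_nm Sampling grid, default 380-780 nm step 1.
#' @return An [spd] with unit integral.
#' @export
lamp_spd <- function(class, wavelength_nm = 380:780) {
  wl <- wavelength_nm
  p <- switch(match.arg(class, lamp_classes()),
    lps = lamp_curve(wl, 589.3, 1, 2),
    hps = lamp_curve(wl, c(498, 569, 589.3, 616, 498),
                     c(0.10, 0.45, 1.00, 0.45, 0.05),
                     c(3, 4, 9, 5, 40)),
    mercury = lamp_curve(wl, c(404.7, 435.8, 546.1, 577, 579.1),
                         c(0.35, 0.75, 1.00, 0.45, 0.45),
                         c(2.5, 2.5, 2.5, 2.5, 2.5)),
    metal_halide = lamp_curve(wl, c(404.7, 435.8, 546.1, 577, 540),
                              c(0.20, 0.45, 0.60, 0.35, 0.50),
                              c(2.5, 2.5, 2.5, 2.5, 80)),
    fluorescent = lamp_curve(wl, c(435.8, 487, 543, 611, 580),
                             c(0.60, 0.30, 1.00, 0.90, 0.12),
                             c(4, 5, 4, 4, 70)),
    led_3000k = lamp_curve(wl, c(450, 600), c(0.35, 1.00), c(12, 65)),
    led_4000k = lamp_curve(wl, c(450, 570), c(0.70, 1.00), c(12, 60))
  )
  total <- pracma::trapz(wl, p)
  spd(wl, p / total, name = class)
}

#' Modelled lamp-spectrum library
#'
#' The pure lamp classes plus seeded pairwise mixtures, used to (re)fit the
#' colour-ratio to biological-index relationships. Mixture weights are drawn
#' uniformly; with the default `n_mixtures` the library has
#' `7 + n_mixtures >= 20` members spanning sodium, mercury, metal-halide,
#' fluorescent and LED classes.
#'
#' @param n_mixtures Number of random pairwise mixtures to add (default 21).
#' @param seed Integer seed for mixture draws.
#' @param wavelength_nm Sampling grid passed to [lamp_spd()].
#' @return List of [spd] objects.
#' @export
lamp_library <- function(n_mixtures = 21, seed = 1, wavelength_nm = 380:780) {
  classes <- lamp_classes()
  pure <- lapply(classes, lamp_spd, wavelength_nm = wavelength_nm)
  names(pure) <- classes
  set.seed(seed)
  mixes <- vector("list", n_mixtures)
  for (i in seq_len(n_mixtures)) {
    pair <- sample(classes, 2)
    w <- stats::runif(1, 0.15, 0.85)
    mixes[[i]] <- mix_spd(pure[pair], c(w, 1 - w),
                          name = sprintf("%s+%s", pair[1], pair[2]))
  }
  c(pure, mixes)
}
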
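# colour-ratio grids and the outlier / VIIRS-threshold masks.
# Masking never alters surviving ratio values and is order-independent:
# each filter only adds reason codes to currently-valid pixels.

#' Compute colour-ratio grids from a mosaic
#'
#' Per-pixel B/G, G/R and R/G band ratios. Pixels with any nonpositive band
#' are masked `unlit`; pixels already masked in the mosaic keep their reason.
#'
#' @param mosaic An [alan_grid] with layers `r`, `g`, `b`.
#' @return An [alan_grid] of class layers `b_over_g`, `g_over_r`, `r_over_g`
#'   with a reason-code mask.
#' @export
compute_ratios <- function(mosaic) {
  r <- mosaic$layers$r; g <- mosaic$layers$g; b <- mosaic$layers$b
  mask <- mosaic$mask
  bad <- (!is.finite(r) | !is.finite(g) | !is.finite(b) |
            r <= 0 | g <= 0 | b <= 0)
  mask[bad & mask == 0L] <- mask_codes()[["unlit"]]
  ok <- mask == 0L
  bg <- gr <- rg <- matrix(NA_real_, nrow(mask), ncol(mask))
  bg[ok] <- b[ok] / g[ok]
  gr[ok] <- g[ok] / r[ok]
  rg[ok] <- r[ok] / g[ok]
  alan_grid(list(b_over_g = bg, g_over_r = gr, r_over_g = rg),
            crs = mosaic$crs, origin = mosaic$origin, res = mosaic$res,
            mask = mask)
}

#' Remove colour-ratio outliers
#'
#' Masks low signal-to-noise pixels on the B/G versus G/R diagram: a valid
#' pixel is flagged `outlier` if B/G exceeds `bg_max`, or G/R exceeds
#' `gr_max`, or R/G exceeds `rg_max` (strict inequalities: a pixel exactly at
#' a threshold is retained). The disjunctive rule (any violation masks) is
#' the default; `conjunctive = TRUE` masks only pixels violating a ratio
#' threshold and the R/G threshold together.
#'
#' @param rg A ratio grid from [compute_ratios()].
#' @param bg_max,gr_max,rg_max Thresholds (defaults 1.2, 1.2, 6).
#' @param conjunctive Use the conjunctive reading of the rule.
#' @return The grid with outliers masked; ratio values of surviving pixels
#'   are untouched.
#' @export
filter_outliers <- function(rg, bg_max = 1.2, gr_max = 1.2, rg_max = 6,
                            conjunctive = FALSE) {
  ok <- rg$mask == 0L
  v_bg <- rg$layers$b_over_g > bg_max
  v_gr <- rg$layers$g_over_r > gr_max
  v_rg <- rg$layers$r_over_g > rg_max
  viol <- if (conjunctive) (v_bg | v_gr) & v_rg else v_bg | v_gr | v_rg
  viol[is.na(viol)] <- FALSE
  rg$mask[ok & viol] <- mask_codes()[["outlier"]]
  rg
}

#' Mask pixels below the VIIRS radiance threshold
#'
#' Pixels whose co-located VIIRS value is strictly below the threshold
#' (default 0.5 nW cm-2 sr-1) are flagged `below_viirs_threshold`, avoiding
#' calibration issues from natural skyglow; a pixel exactly at the threshold
#' is retained.
#'
#' @param rg A ratio grid.
#' @param viirs An [alan_grid] with layer `viirs`, co-registered with `rg`.
#' @param threshold Radiance threshold (nW cm-2 sr-1).
#' @return The masked grid.
#' @export
apply_viirs_mask <- function(rg, viirs, threshold = 0.5) {
  check_congruent(rg, viirs)
  low <- viirs$layers$viirs < threshold
  rg$mask[rg$mask == 0L & low] <- mask_codes()[["below_viirs_threshold"]]
  rg
}
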
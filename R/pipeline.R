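# end-to-end driver: simulate -> calibrate -> mosaic per epoch -> ratios and
# masks -> intensities and indices -> epoch comparison report.

#' Pipeline configuration
#'
#' Everything a full synthetic run needs. All randomness derives from `seed`,
#' so a rerun with the same configuration is bit-identical.
#'
#' @param grid_shape Analysis grid `c(rows, cols)` (500-m pixels).
#' @param n_cities City blobs in the synthetic scene.
#' @param frames_per_epoch Camera frames rendered per epoch.
#' @param epoch_shift Fraction of lit pixels converted to LED in epoch 2.
#' @param seed Integer master seed.
#' @param distortions A [distortion_config()].
#' @param thresholds Filter thresholds: `bg`, `gr`, `rg` (outlier rule) and
#'   `viirs` (radiance mask, nW cm-2 sr-1).
#' @param coeffs Intensity-model coefficients ([default_coefficients()]), or
#'   a path to a JSON coefficient file.
#' @param georef_method `"affine"` or `"tps"`.
#' @param n_regions Regions for the zonal summary (0 to skip).
#' @param out_dir Optional output directory; when set, grids, tables and the
#'   manifest are written there.
#' @param origin,res Grid transform.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(grid_shape = c(160, 160), n_cities = 8,
                            frames_per_epoch = 6, epoch_shift = 0.5,
                            seed = 1,
                            distortions = distortion_config(),
                            thresholds = list(bg = 1.2, gr = 1.2, rg = 6,
                                              viirs = 0.5),
                            coeffs = default_coefficients(),
                            georef_method = "affine",
                            n_regions = 0, out_dir = NULL,
                            origin = c(4e6, 3.5e6), res = 500) {
  stopifnot(all(unlist(thresholds) > 0), res > 0)
  if (is.character(coeffs)) coeffs <- read_coefficients(coeffs)
  check_coeffs(coeffs)
  structure(list(grid_shape = as.integer(grid_shape), n_cities = n_cities,
                 frames_per_epoch = frames_per_epoch,
                 epoch_shift = epoch_shift, seed = as.integer(seed),
                 distortions = distortions, thresholds = thresholds,
                 coeffs = coeffs, georef_method = georef_method,
                 n_regions = n_regions, out_dir = out_dir,
                 origin = origin, res = res),
            class = "pipeline_config")
}

# rolling polynomial hash (mod 2^31 - 1) of a configuration's deparsed form
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

derive_seed <- function(seed, offset) (seed * 1009L + offset) %% 2147483647L

# tiled acquisition geometries covering the grid with overlap.
# The acquisition plan (tiling, angles, optics, settings) is shared between
# epochs so that epoch contrasts reflect the scene, not the sampling;
# only timestamps are epoch-specific.
make_geometries <- function(grid_shape, n_frames, epoch, seed) {
  set.seed(derive_seed(seed, 101L))
  tiles_r <- max(1L, floor(sqrt(n_frames)))
  tiles_c <- ceiling(n_frames / tiles_r)
  base_r <- ceiling(grid_shape[1] / tiles_r)
  base_c <- ceiling(grid_shape[2] / tiles_c)
  fr <- min(grid_shape[1], ceiling(base_r * 1.3))
  fc <- min(grid_shape[2], ceiling(base_c * 1.3))
  geoms <- vector("list", n_frames)
  k <- 0
  for (i in seq_len(tiles_r)) for (j in seq_len(tiles_c)) {
    if (k >= n_frames) break
    k <- k + 1
    r0 <- min(max(1L, (i - 1L) * base_r + 1L), grid_shape[1] - fr + 1L)
    c0 <- min(max(1L, (j - 1L) * base_c + 1L), grid_shape[2] - fc + 1L)
    geoms[[k]] <- acquisition_geometry(
      angle_deg = stats::runif(1, 5, 35),
      focal_mm = sample(c(85, 180, 400), 1),
      origin_px = c(r0, c0), frame_shape = c(fr, fc),
      timestamp = NA,
      exposure_s = sample(c(0.25, 1 / 3, 0.5), 1),
      iso = sample(c(800, 1600), 1),
      lens_t = stats::runif(1, 0.85, 1),
      frame_id = sprintf("%s_f%02d", epoch, k))
  }
  geoms <- geoms[seq_len(k)]
  set.seed(derive_seed(seed, if (epoch == "epoch1") 102L else 203L))
  for (i in seq_along(geoms))
    geoms[[i]]$timestamp <- if (epoch == "epoch1")
      stats::runif(1, 2012, 2013.9) else stats::runif(1, 2014, 2020.9)
  geoms
}

# instrumental constants from a dedicated calibration acquisition: estimated
# once per instrument and applied to every focal frame of both epochs, as in
# the star-based absolute calibration of the real workflow
calibrate_instrument <- function(map, camera, config) {
  model <- calibration_model_from_config(config$distortions)
  geom <- make_geometries(config$grid_shape, 1L, "epoch1", config$seed)[[1]]
  geom$frame_id <- "calibration"
  frame <- render_frame(map, camera, geom, config$distortions,
                        seed = derive_seed(config$seed, 99L))
  frame <- correct_linearity(frame, model)
  frame <- correct_flatfield(frame, model)
  frame <- spectral_characterize(frame, model)
  model$constants <- photometric_calibrate(frame, frame$truth$stars, model)
  model
}

# auto-exposure: choose the exposure time that puts the brightest scene
# pixel of the frame window at the sensor's linearity knee, as a night
# photographer protecting highlights would. Exposures are set from the
# epoch-1 scene for both epochs so the acquisition plan stays shared.
set_auto_exposure <- function(geoms, map, camera, distortions) {
  d <- distortions
  s <- class_band_signals(map$classes, camera)
  knee <- d$nonlinearity$knee_frac * d$nonlinearity$fullwell
  if (!is.finite(knee)) return(geoms)
  for (i in seq_along(geoms)) {
    g <- geoms[[i]]
    rows <- g$origin_px[1]:(g$origin_px[1] + g$frame_shape[1] - 1)
    cols <- g$origin_px[2]:(g$origin_px[2] + g$frame_shape[2] - 1)
    W <- matrix(map$weights[rows, cols, ], length(rows) * length(cols),
                length(map$classes))
    band_max <- pmax((W %*% s[, "r"])[, 1], (W %*% s[, "g"])[, 1],
                     (W %*% s[, "b"])[, 1])
    Lmax <- max(band_max * as.vector(map$scale[rows, cols]), 1e-6)
    geoms[[i]]$exposure_s <- knee /
      (d$gain * (g$iso / d$ref_iso) * g$lens_t * Lmax)
  }
  geoms
}

process_epoch <- function(map, viirs, camera, config, epoch, model, geoms) {
  aligned <- vector("list", length(geoms))
  for (i in seq_along(geoms)) {
    fid <- geoms[[i]]$frame_id
    aligned[[i]] <- tryCatch({
      frame <- render_frame(map, camera, geoms[[i]], config$distortions,
                            seed = derive_seed(config$seed,
                                               i + if (epoch == "epoch1")
                                                 1000L else 2000L),
                            cloud_seed = derive_seed(config$seed, i + 500L))
      rframe <- calibrate_frame(frame, model, viirs = viirs)
      georeference(rframe, config$grid_shape, method = config$georef_method)
    }, error = function(e)
      stop("stage calibrate/georeference failed for frame ", fid, ": ",
           conditionMessage(e)))
  }
  policy <- if (epoch == "epoch1") "pre" else "post"
  mosaic <- composite(aligned, epoch_policy = policy, crs = map$crs,
                      origin = map$origin, res = map$res)
  rg <- compute_ratios(mosaic)
  rg <- filter_outliers(rg, config$thresholds$bg, config$thresholds$gr,
                        config$thresholds$rg)
  rg <- apply_viirs_mask(rg, viirs, config$thresholds$viirs)
  list(mosaic = mosaic, ratios = rg)
}

#' Run the full synthetic pipeline
#'
#' Simulates the two-epoch scene, renders and calibrates frames, builds the
#' per-epoch mosaics, computes masked colour-ratio grids, VIIRS-corrected
#' intensity grids (G, B, phototaxis-weighted) and a melatonin-suppression
#' index grid, and compares all of these between epochs. Deterministic given
#' the configuration seed.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result`: `maps`, `viirs`, `mosaics`,
#'   `ratios`, `intensity`, `index` (per-epoch grid lists), `comparisons`
#'   (named [compare_epochs()] results), `report`
#'   ([distribution_report()] output), optional `zonal` table, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  camera <- default_camera()
  maps <- make_lamp_maps(config$n_cities, config$grid_shape,
                         config$epoch_shift,
                         seed = derive_seed(config$seed, 1L),
                         origin = config$origin, res = config$res)
  viirs <- lapply(maps, render_viirs, camera = camera)
  model <- calibrate_instrument(maps$epoch1, camera, config)
  geoms <- lapply(c(epoch1 = "epoch1", epoch2 = "epoch2"), function(e)
    set_auto_exposure(make_geometries(config$grid_shape,
                                      config$frames_per_epoch, e,
                                      config$seed),
                      maps$epoch1, camera, config$distortions))
  epochs <- lapply(c(epoch1 = "epoch1", epoch2 = "epoch2"), function(e)
    process_epoch(maps[[e]], viirs[[e]], camera, config, e, model,
                  geoms[[e]]))
  # index model: MSI from B/G over the modelled lamp library
  msi_model <- fit_ratio_index_curve(
    lamp_library(seed = derive_seed(config$seed, 7L)),
    predictor = "b_over_g", response = "msi", camera = camera,
    n_boot = 200, seed = derive_seed(config$seed, 8L))
  grids <- list()
  for (e in names(epochs)) {
    rg <- epochs[[e]]$ratios
    grids[[e]] <- list(
      b_over_g = alan_grid(rg$layers["b_over_g"], rg$crs, rg$origin, rg$res,
                           rg$mask),
      g_over_r = alan_grid(rg$layers["g_over_r"], rg$crs, rg$origin, rg$res,
                           rg$mask),
      g_intensity = estimate_intensity(viirs[[e]], rg, "G", config$coeffs),
      b_intensity = estimate_intensity(viirs[[e]], rg, "B", config$coeffs),
      p_intensity = estimate_intensity(viirs[[e]], rg, "P", config$coeffs),
      msi = index_grid(rg, msi_model))
  }
  quantities <- names(grids$epoch1)
  comparisons <- list(); samples <- list()
  for (q in quantities) {
    pre <- valid_values(grids$epoch1[[q]])
    post <- valid_values(grids$epoch2[[q]])
    comparisons[[q]] <- compare_epochs(pre, post, quantity = q)
    samples[[q]] <- list(comparison = comparisons[[q]], pre = pre,
                         post = post)
  }
  report <- distribution_report(samples)
  zonal <- NULL
  if (config$n_regions > 0) {
    regions <- make_regions(config$n_regions, epochs$epoch1$ratios,
                            seed = derive_seed(config$seed, 9L))
    zonal <- zonal_summary(grids$epoch1$g_over_r, grids$epoch2$g_over_r,
                           regions)
  }
  accounting <- lapply(epochs, function(e)
    table(factor(e$ratios$mask, levels = mask_codes(),
                 labels = names(mask_codes()))))
  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   package_version = as.character(
                     utils::packageVersion("alanrisk")),
                   frames = lapply(epochs, function(e)
                     attr(e$mosaic, "frame_ids")),
                   pixel_accounting = lapply(accounting, as.list),
                   msi_model = unclass(msi_model)[c("coefficients", "rmse",
                                                    "family", "domain")])
  result <- structure(list(maps = maps, viirs = viirs,
                           mosaics = lapply(epochs, `[[`, "mosaic"),
                           ratios = lapply(epochs, `[[`, "ratios"),
                           grids = grids, comparisons = comparisons,
                           report = report, zonal = zonal,
                           msi_model = msi_model, manifest = manifest,
                           config = config),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result: %dx%d grid, %d frames/epoch, shift %.2f>\n",
              x$config$grid_shape[1], x$config$grid_shape[2],
              x$config$frames_per_epoch, x$config$epoch_shift))
  for (cmp in x$comparisons) print(cmp)
  invisible(x)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (e in names(result$mosaics)) {
    write_grid(result$mosaics[[e]], file.path(out_dir,
                                              paste0("mosaic_", e, ".rds")))
    write_grid(result$ratios[[e]], file.path(out_dir,
                                             paste0("ratios_", e, ".rds")))
    for (q in names(result$grids[[e]]))
      write_grid(result$grids[[e]][[q]],
                 file.path(out_dir, sprintf("%s_%s.rds", q, e)))
  }
  utils::write.csv(result$report$table,
                   file.path(out_dir, "comparisons.csv"), row.names = FALSE)
  if (!is.null(result$zonal))
    utils::write.csv(result$zonal, file.path(out_dir, "zonal.csv"),
                     row.names = FALSE)
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
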
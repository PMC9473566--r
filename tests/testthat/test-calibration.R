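cam <- default_camera()

test_that("linearity correction inverts the sensor roll-off", {
  maps <- make_lamp_maps(3, c(100, 100), 0, seed = 4)
  geom <- acquisition_geometry(0, 180, c(3, 3), c(96, 96), 2012.2, 0.25,
                               800, 1, "fl")
  nl <- list(fullwell = 16383, knee_frac = 0.8, power = 0.6)
  model <- calibration_model(nonlinearity = nl, vignette = c(0, 0))
  # identity curve leaves the frame unchanged
  off <- distortion_config_off(n_stars = 0)
  f0 <- render_frame(maps$epoch1, cam, geom, off, seed = 1)
  ident <- calibration_model(nonlinearity = list(fullwell = Inf,
                                                 knee_frac = 1, power = 1),
                             vignette = c(0, 0))
  expect_identical(correct_linearity(f0, ident)$counts, f0$counts)
  # known roll-off round-trips within 1% below saturation
  dn <- distortion_config_off(nonlinearity = nl, n_stars = 0)
  fn <- render_frame(maps$epoch1, cam, geom, dn, seed = 1)
  corrected <- correct_linearity(fn, model)
  ok <- corrected$mask == 0L & f0$counts[, , 1] > 1
  expect_lt(max(abs(corrected$counts[, , 1][ok] - f0$counts[, , 1][ok]) /
                  f0$counts[, , 1][ok]), 0.01)
  # a count exactly at the knee is unchanged
  knee <- nl$knee_frac * nl$fullwell
  fk <- f0; fk$counts[] <- knee
  expect_equal(correct_linearity(fk, model)$counts[1, 1, 1], knee,
               tolerance = 1e-12)
  # counts at the full-well response are flagged saturated
  fs <- f0; fs$counts[5, 5, 2] <- knee * (nl$fullwell / knee)^nl$power
  expect_equal(correct_linearity(fs, model)$mask[5, 5],
               unname(mask_codes()["saturated"]))
})

test_that("flat-field correction removes vignetting", {
  maps <- make_lamp_maps(3, c(100, 100), 0, seed = 4)
  geom <- acquisition_geometry(0, 180, c(3, 3), c(96, 96), 2012.2, 0.25,
                               800, 1, "ff")
  dv <- distortion_config_off(vignette = c(0.30, 0.15), n_stars = 0)
  fv <- render_frame(maps$epoch1, cam, geom, dv, seed = 1)
  model <- calibration_model(vignette = c(0.30, 0.15),
                             nonlinearity = list(fullwell = Inf,
                                                 knee_frac = 1, power = 1))
  fc <- correct_flatfield(fv, model)
  f0 <- render_frame(maps$epoch1, cam, geom,
                     distortion_config_off(n_stars = 0), seed = 1)
  lit <- maps$epoch1$scale[3:98, 3:98] > 0.5
  expect_equal(fc$counts[, , 2][lit], f0$counts[, , 2][lit],
               tolerance = 1e-9)
  # flat-field of 1 is the identity; 0.5 doubles the count
  ident <- calibration_model(flatfield = matrix(1, 96, 96))
  expect_equal(correct_flatfield(fv, ident)$counts, fv$counts)
  half <- calibration_model(flatfield = matrix(0.5, 96, 96))
  expect_equal(correct_flatfield(f0, half)$counts, f0$counts * 2)
  bad <- calibration_model(flatfield = matrix(1, 96, 96))
  bad$flatfield[3, 3] <- 0
  expect_error(correct_flatfield(fv, bad), "positive")
})

test_that("spectral characterisation inverts channel crosstalk", {
  M <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0.1, 0.9))  # 10% G leak into B
  maps <- make_lamp_maps(3, c(100, 100), 0, seed = 4)
  geom <- acquisition_geometry(0, 180, c(3, 3), c(96, 96), 2012.2, 0.25,
                               800, 1, "fx")
  f0 <- render_frame(maps$epoch1, cam, geom,
                     distortion_config_off(n_stars = 0), seed = 1)
  fx <- render_frame(maps$epoch1, cam, geom,
                     distortion_config_off(crosstalk = M, n_stars = 0),
                     seed = 1)
  model <- calibration_model(crosstalk = M)
  rec <- spectral_characterize(fx, model)
  expect_equal(rec$counts, f0$counts, tolerance = 1e-6)
  # identity matrix is the identity; zeros stay zeros
  ident <- calibration_model(crosstalk = diag(3))
  expect_equal(spectral_characterize(fx, ident)$counts, fx$counts)
  fz <- f0; fz$counts[] <- 0
  expect_true(all(spectral_characterize(fz, model)$counts == 0))
  expect_error(calibration_model(crosstalk = matrix(1, 3, 3)), "singular")
})

test_that("photometric calibration recovers the instrumental constant", {
  maps <- make_lamp_maps(3, c(120, 120), 0, seed = 4)
  d <- distortion_config()
  geom <- acquisition_geometry(10, 180, c(5, 5), c(110, 110), 2012.2, 0.25,
                               800, 0.95, "fp")
  model <- calibration_model_from_config(d)
  frame <- render_frame(maps$epoch1, cam, geom, d, seed = 21)
  frame <- spectral_characterize(correct_flatfield(correct_linearity(frame,
                                                                     model),
                                                   model), model)
  k <- photometric_calibrate(frame, frame$truth$stars, model)
  expect_lt(max(abs(k * d$gain - 1)), 0.02)
  # doubling the exposure leaves the constants unchanged within 1%
  geom2 <- geom; geom2$exposure_s <- 0.5
  frame2 <- render_frame(maps$epoch1, cam, geom2, d, seed = 21)
  frame2 <- spectral_characterize(correct_flatfield(correct_linearity(frame2,
                                                                      model),
                                                    model), model)
  k2 <- photometric_calibrate(frame2, frame2$truth$stars, model)
  expect_lt(max(abs(k2 / k - 1)), 0.01)
})

test_that("saturated reference sources are excluded, too few is an error", {
  nl <- list(fullwell = 1000, knee_frac = 0.8, power = 0.6)
  model <- calibration_model(nonlinearity = nl)
  counts <- array(0, c(60, 60, 3))
  sat_level <- 800 * (1000 / 800)^0.6
  sources <- data.frame(row = c(15, 30, 45), col = c(15, 30, 45),
                        r = c(5, 5, 5), g = c(5, 5, 5), b = c(5, 5, 5))
  for (i in 1:3) counts[sources$row[i], sources$col[i], ] <- 500
  counts[15, 15, 2] <- sat_level  # first source clipped in G
  geom <- acquisition_geometry(0, 180, c(1, 1), c(60, 60), 2012, 0.25, 200,
                               1, "fs")
  frame <- structure(list(counts = counts, geometry = geom,
                          truth = list()), class = "raw_frame")
  frame <- correct_linearity(frame, model)
  expect_error(photometric_calibrate(frame, sources, model),
               "fewer than 3 usable")
  expect_error(photometric_calibrate(frame, sources[1:2, ], model),
               "fewer than 3")
})

test_that("radiometric and atmospheric corrections follow the settings", {
  rad <- array(1, c(10, 10, 3))
  cps <- data.frame(frame_row = c(1, 1, 10, 10), frame_col = c(1, 10, 1, 10),
                    map_row = c(1, 1, 10, 10), map_col = c(1, 10, 1, 10))
  rf <- make_radiance_frame(rad, cps)
  model <- calibration_model(t_atm = c(r = 1, g = 1, b = 0.8))
  out <- atmospheric_correct(rf, model)
  expect_equal(out$radiance[, , 3], rad[, , 3] * 1.25)   # t = 0.8 at nadir
  expect_equal(out$radiance[, , 1], rad[, , 1])          # t = 1 is identity
  # zero counts give zero radiance; missing metadata is a named error
  maps <- make_lamp_maps(3, c(100, 100), 0, seed = 4)
  geom <- acquisition_geometry(0, 180, c(3, 3), c(96, 96), 2012.2, 0.25,
                               800, 1, "fr")
  f0 <- render_frame(maps$epoch1, cam, geom,
                     distortion_config_off(n_stars = 0), seed = 1)
  f0$counts[] <- 0
  rr <- radiometric_correct(f0, c(r = 1, g = 1, b = 1) / 540,
                            calibration_model())
  expect_true(all(rr$radiance == 0))
  f0$geometry$exposure_s <- NA
  expect_error(radiometric_correct(f0, c(r = 1, g = 1, b = 1),
                                   calibration_model()), "exposure_s")
})

test_that("the same scene at ISO 800 and ISO 1600 calibrates identically", {
  maps <- make_lamp_maps(3, c(120, 120), 0, seed = 4)
  d <- distortion_config_off(n_stars = 20)
  model <- calibration_model_from_config(d)
  g1 <- acquisition_geometry(0, 180, c(5, 5), c(110, 110), 2012.2, 0.25,
                             800, 1, "fi1")
  g2 <- g1; g2$iso <- 1600
  r1 <- calibrate_frame(render_frame(maps$epoch1, cam, g1, d, seed = 3),
                        model)
  r2 <- calibrate_frame(render_frame(maps$epoch1, cam, g2, d, seed = 3),
                        model)
  lit <- maps$epoch1$scale[5:114, 5:114] > 0.5
  expect_equal(r1$radiance[, , 2][lit], r2$radiance[, , 2][lit],
               tolerance = 1e-6)
})

test_that("cloud masking flags occluded pixels against VIIRS", {
  maps <- make_lamp_maps(4, c(120, 120), 0, seed = 6)
  viirs <- render_viirs(maps$epoch1)
  d <- distortion_config()
  geom <- acquisition_geometry(10, 180, c(5, 5), c(110, 110), 2012.2, 0.25,
                               800, 0.95, "fc")
  model <- calibration_model_from_config(d)
  frame <- render_frame(maps$epoch1, cam, geom, d, seed = 13)
  rf <- calibrate_frame(frame, model, viirs = viirs)
  vwin <- viirs$layers$viirs[5:114, 5:114]
  relevant <- frame$truth$cloud & vwin >= 0.5
  expect_gt(sum(relevant), 50)
  expect_gte(mean(rf$mask[relevant] == mask_codes()["cloud"]), 0.95)
  # an empty explicit mask changes nothing; a full one invalidates everything
  rf2 <- calibrate_frame(frame, model,
                         cloud_mask = matrix(FALSE, 110, 110))
  expect_true(all(rf2$mask[relevant] != mask_codes()["cloud"]))
  rf3 <- calibrate_frame(frame, model, cloud_mask = matrix(TRUE, 110, 110))
  expect_true(all(rf3$mask != 0L))
  expect_error(mask_clouds(rf), "either")
})

test_that("the correction order matters and the chain is homogeneous", {
  maps <- make_lamp_maps(3, c(100, 100), 0, seed = 4)
  nl <- list(fullwell = 16383, knee_frac = 0.8, power = 0.6)
  dd <- distortion_config_off(vignette = c(0.30, 0.15), nonlinearity = nl,
                              n_stars = 0)
  geom <- acquisition_geometry(0, 180, c(3, 3), c(96, 96), 2012.2, 0.25,
                               800, 1, "fo")
  f0 <- render_frame(maps$epoch1, cam, geom,
                     distortion_config_off(n_stars = 0), seed = 1)
  fd <- render_frame(maps$epoch1, cam, geom, dd, seed = 1)
  model <- calibration_model(nonlinearity = nl, vignette = c(0.30, 0.15))
  right <- correct_flatfield(correct_linearity(fd, model), model)
  wrong <- correct_linearity(correct_flatfield(fd, model), model)
  ok <- right$mask == 0L & wrong$mask == 0L & f0$counts[, , 1] > 1
  err <- function(f) sqrt(mean((f$counts[, , 1][ok] -
                                  f0$counts[, , 1][ok])^2))
  expect_gt(err(wrong), 2 * err(right))
  # homogeneity: doubling scene radiance doubles recovered radiance
  d <- distortion_config_off(vignette = c(0.3, 0.15), n_stars = 15)
  mfull <- calibration_model_from_config(d)
  maps2 <- maps$epoch1
  maps2$scale <- maps2$scale * 2
  r1 <- calibrate_frame(render_frame(maps$epoch1, cam, geom, d, seed = 2),
                        mfull)
  r2 <- calibrate_frame(render_frame(maps2, cam, geom, d, seed = 2), mfull)
  lit <- maps$epoch1$scale[3:98, 3:98] > 0.5
  expect_lt(max(abs(r2$radiance[, , 2][lit] / r1$radiance[, , 2][lit] - 2)),
            0.02)
  # no negative radiances in valid pixels
  expect_true(all(r1$radiance[, , 1][r1$mask == 0L] >= 0))
})
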
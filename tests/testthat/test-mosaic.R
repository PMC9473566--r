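test_that("identity control points reproduce the raster", {
  set.seed(3)
  rad <- array(runif(40 * 40 * 3), c(40, 40, 3))
  pts <- cbind(runif(8, 2, 39), runif(8, 2, 39))
  cps <- data.frame(frame_row = pts[, 1], frame_col = pts[, 2],
                    map_row = pts[, 1], map_col = pts[, 2])
  rf <- make_radiance_frame(rad, cps)
  al <- georeference(rf, c(40, 40))
  expect_equal(al$layers$g, rad[, , 2])
  expect_lt(al$rmse, 1e-9)
  expect_true(all(al$mask == 0L))
})

test_that("affine georeferencing reports the planted jitter RMSE", {
  # the control-point residual is the georeferencing error estimate;
  # with ~4 px planted jitter it should come back as about 4 px
  set.seed(10)
  n <- 40
  pts <- cbind(runif(n, 1, 100), runif(n, 1, 100))
  jit <- 4 / sqrt(2)
  cps <- data.frame(frame_row = pts[, 1], frame_col = pts[, 2],
                    map_row = pts[, 1] + 17 + rnorm(n, 0, jit),
                    map_col = pts[, 2] - 9 + rnorm(n, 0, jit))
  rf <- make_radiance_frame(array(1, c(100, 100, 3)), cps)
  al <- georeference(rf, c(130, 130))
  expect_gt(al$rmse, 2.8)
  expect_lt(al$rmse, 5.2)
  # collinear control points are rejected
  bad <- data.frame(frame_row = 1:6, frame_col = 1:6,
                    map_row = 1:6, map_col = 1:6)
  expect_error(georeference(rf, c(130, 130), cps = bad), "collinear")
  expect_error(georeference(rf, c(130, 130), cps = cps[1:3, ]), ">= 4")
})

test_that("thin-plate splines track a smooth nonlinear warp", {
  set.seed(4)
  n <- 16
  pts <- cbind(runif(n, 5, 95), runif(n, 5, 95))
  warp <- function(p) cbind(p[, 1] + 3 * sin(p[, 2] / 25),
                            p[, 2] + 8e-4 * p[, 1]^2)
  w <- warp(pts)
  cps <- data.frame(frame_row = pts[, 1], frame_col = pts[, 2],
                    map_row = w[, 1], map_col = w[, 2])
  rf <- make_radiance_frame(array(1, c(100, 100, 3)), cps)
  tps <- georeference(rf, c(120, 120), method = "tps")
  aff <- georeference(rf, c(120, 120), method = "affine")
  expect_lt(tps$rmse, 1)      # below the nearest-neighbour pixel size
  expect_gt(aff$rmse, tps$rmse)
})

test_that("precedence is lexicographic in angle, focal length, offset, time", {
  gA <- acquisition_geometry(10, 180, c(1, 1), c(10, 10), 2015, 0.25, 800,
                             1, "A")
  gB <- acquisition_geometry(40, 180, c(1, 1), c(10, 10), 2015, 0.25, 800,
                             1, "B")
  expect_true(precedence_wins(precedence_score(gA, 5),
                              precedence_score(gB, 1)))
  gC <- acquisition_geometry(10, 400, c(1, 1), c(10, 10), 2015, 0.25, 800,
                             1, "C")
  gD <- acquisition_geometry(10, 50, c(1, 1), c(10, 10), 2015, 0.25, 800,
                             1, "D")
  expect_true(precedence_wins(precedence_score(gC, 5),
                              precedence_score(gD, 1)))
  # nearer the frame centre wins when optics tie
  expect_true(precedence_wins(precedence_score(gA, 2),
                              precedence_score(gA, 7)))
  # more recent wins under the post policy only
  gE <- gA; gE$timestamp <- 2019
  expect_true(precedence_wins(precedence_score(gE, 5, "post"),
                              precedence_score(gA, 5, "post")))
  expect_false(precedence_wins(precedence_score(gE, 5, "pre"),
                               precedence_score(gA, 5, "pre")))
  # full tie: neither wins (composite then falls back to frame ID order)
  expect_false(precedence_wins(precedence_score(gA, 5),
                               precedence_score(gA, 5)))
})

# two overlapping aligned frames with distinct watermark values
overlap_pair <- function(angle_a = 10, angle_b = 25) {
  mk <- function(value, rows, id, angle) {
    rad <- array(value, c(30, 30, 3))
    pts <- cbind(c(2, 2, 28, 28, 15), c(2, 28, 2, 28, 15))
    cps <- data.frame(frame_row = pts[, 1], frame_col = pts[, 2],
                      map_row = pts[, 1] + rows, map_col = pts[, 2])
    georeference(make_radiance_frame(rad, cps, angle = angle, frame_id = id),
                 c(50, 30))
  }
  list(a = mk(1, 0, "fa", angle_a), b = mk(2, 20, "fb", angle_b))
}

test_that("composite picks one whole-pixel winner and keeps provenance", {
  pair <- overlap_pair()
  m <- composite(list(pair$a, pair$b))
  ids <- attr(m, "frame_ids")
  # single-frame mosaic equals the frame over its footprint
  solo <- composite(list(pair$a))
  expect_equal(solo$layers$g[pair$a$mask == 0L],
               pair$a$layers$g[pair$a$mask == 0L])
  # overlap rows 21-30 go entirely to the lower-angle frame a
  ov <- m$mask == 0L & pair$a$mask == 0L & pair$b$mask == 0L
  expect_true(any(ov))
  expect_true(all(m$layers$r[ov] == 1))
  expect_true(all(ids[m$layers$provenance[ov]] == "fa"))
  # non-overlap pixels come from their own frame; no value mixes frames
  expect_true(all(m$layers$r[m$mask == 0L] %in% c(1, 2)))
  only_b <- m$mask == 0L & pair$a$mask != 0L
  expect_true(all(m$layers$r[only_b] == 2))
  expect_error(composite(list()), "empty")
})

test_that("composite is idempotent and order-independent", {
  pair <- overlap_pair()
  m1 <- composite(list(pair$a, pair$b))
  m2 <- composite(list(pair$b, pair$a))
  expect_identical(m1$layers, m2$layers)
  expect_identical(m1$mask, m2$mask)
  # compositing a mosaic with itself returns itself
  as_frame <- function(m, id) {
    structure(list(layers = m$layers[c("r", "g", "b")], mask = m$mask,
                   center_offset = matrix(1, nrow(m$mask), ncol(m$mask)),
                   geometry = acquisition_geometry(10, 180, c(1, 1),
                                                   dim(m$mask), 2015, 0.25,
                                                   800, 1, id)),
              class = "aligned_frame")
  }
  twice <- composite(list(as_frame(m1, "m_1"), as_frame(m1, "m_2")))
  expect_equal(twice$layers$r, m1$layers$r)
  expect_identical(twice$mask == 0L, m1$mask == 0L)
})

test_that("winner-takes-all beats mean-blending on a biased frame pair", {
  # frame a sees the truth; frame b is biased high (e.g. residual
  # calibration error at high airmass). The precedence mosaic should track
  # the truth better than averaging the two frames.
  pair <- overlap_pair()
  truth <- 1
  m <- composite(list(pair$a, pair$b))
  ov <- pair$a$mask == 0L & pair$b$mask == 0L
  blend <- (pair$a$layers$r[ov] + pair$b$layers$r[ov]) / 2
  err_winner <- mean(abs(m$layers$r[ov] - truth))
  err_blend <- mean(abs(blend - truth))
  expect_lt(err_winner, err_blend)
})
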
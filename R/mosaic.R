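# georeferencing (affine / thin-plate spline) and precedence-based
# winner-takes-all compositing onto the analysis grid.

# least-squares affine fit src (n x 2) -> dst (n x 2)
fit_affine <- function(src, dst) {
  X <- cbind(1, src)
  q <- qr(X)
  if (q$rank < 3L) stop("degenerate (collinear) control points")
  beta <- qr.coef(q, dst)
  function(p) cbind(1, p) %*% beta
}

# exact thin-plate spline src -> dst with kernel r^2 log r
fit_tps <- function(src, dst) {
  n <- nrow(src)
  if (n < 6L) stop("thin-plate spline needs >= 6 control points")
  rbf <- function(r2) ifelse(r2 <= 0, 0, 0.5 * r2 * log(r2))  # r^2 log r
  d2 <- as.matrix(stats::dist(src))^2
  K <- rbf(d2) + diag(1e-8, n)
  P <- cbind(1, src)
  if (qr(P)$rank < 3L) stop("degenerate (collinear) control points")
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- rbind(dst, matrix(0, 3, 2))
  coefs <- solve(A, rhs)
  w <- coefs[1:n, , drop = FALSE]
  a <- coefs[(n + 1):(n + 3), , drop = FALSE]
  function(p) {
    d2p <- outer(rowSums(p^2), rep(1, n)) + outer(rep(1, nrow(p)),
                                                  rowSums(src^2)) -
      2 * p %*% t(src)
    rbf(pmax(d2p, 0)) %*% w + cbind(1, p) %*% a
  }
}

#' Georeference a calibrated frame onto the analysis grid
#'
#' Fits the frame-to-grid mapping from ground control points (affine needs
#' >= 4 points; thin-plate spline, with the standard `r^2 log r` kernel,
#' needs >= 6 and falls back to affine below that) and resamples the frame to
#' the grid. Nearest-neighbour resampling is the default so that band ratios
#' are never blended across source pixels; bilinear is available.
#'
#' @param rframe A `radiance_frame` (see [calibrate_frame()]).
#' @param grid_shape `c(rows, cols)` of the analysis grid.
#' @param cps Control points (data frame with `frame_row`, `frame_col`,
#'   `map_row`, `map_col`); default the frame's own.
#' @param method `"affine"` or `"tps"`.
#' @param resampling `"nearest"` or `"bilinear"`.
#' @return Object of class `aligned_frame`: full-grid layers `r`, `g`, `b`,
#'   mask (`off_scene` outside the footprint), `center_offset` (distance of
#'   each grid pixel's source location from the frame centre, in frame
#'   pixels), `geometry`, and `rmse` (control-point residual RMSE in pixels).
#' @export
georeference <- function(rframe, grid_shape, cps = rframe$cps,
                         method = c("affine", "tps"),
                         resampling = c("nearest", "bilinear")) {
  method <- match.arg(method)
  resampling <- match.arg(resampling)
  src <- as.matrix(cps[, c("frame_row", "frame_col")])
  dst <- as.matrix(cps[, c("map_row", "map_col")])
  if (anyDuplicated(round(src, 9))) stop("duplicate frame control points")
  if (nrow(src) < 4L) stop("need >= 4 control points")
  fitter <- if (method == "tps" && nrow(src) >= 6L) fit_tps else fit_affine
  fwd <- fitter(src, dst)
  inv <- fitter(dst, src)
  res <- fwd(src) - dst
  rmse <- sqrt(mean(rowSums(res^2)))
  d <- dim(rframe$radiance)
  gr <- grid_shape[1]; gc <- grid_shape[2]
  # candidate grid pixels: bounding box of the mapped frame corners + margin
  corners <- fwd(rbind(c(1, 1), c(1, d[2]), c(d[1], 1), c(d[1], d[2])))
  rr <- max(1, floor(min(corners[, 1])) - 2):min(gr, ceiling(max(corners[, 1])) + 2)
  cc <- max(1, floor(min(corners[, 2])) - 2):min(gc, ceiling(max(corners[, 2])) + 2)
  gpix <- cbind(rep(rr, length(cc)), rep(cc, each = length(rr)))
  fpix <- inv(gpix)
  layers <- list(r = matrix(NA_real_, gr, gc), g = matrix(NA_real_, gr, gc),
                 b = matrix(NA_real_, gr, gc))
  mask <- matrix(mask_codes()[["off_scene"]], gr, gc)
  offset <- matrix(Inf, gr, gc)
  gflat <- (gpix[, 2] - 1) * gr + gpix[, 1]
  ctr <- (d[1:2] + 1) / 2
  if (resampling == "nearest") {
    fr <- round(fpix[, 1]); fc <- round(fpix[, 2])
    ok <- fr >= 1 & fr <= d[1] & fc >= 1 & fc <= d[2]
    fflat <- (fc[ok] - 1) * d[1] + fr[ok]
    for (b in 1:3) {
      plane <- rframe$radiance[, , b]
      layers[[b]][gflat[ok]] <- plane[fflat]
    }
    mask[gflat[ok]] <- rframe$mask[fflat]
  } else {
    fr <- fpix[, 1]; fc <- fpix[, 2]
    ok <- fr >= 1 & fr <= d[1] & fc >= 1 & fc <= d[2]
    r0 <- pmin(pmax(floor(fr[ok]), 1), d[1] - 1); c0 <- pmin(pmax(floor(fc[ok]), 1), d[2] - 1)
    tr <- fr[ok] - r0; tc <- fc[ok] - c0
    for (b in 1:3) {
      plane <- rframe$radiance[, , b]
      v <- plane[cbind(r0, c0)] * (1 - tr) * (1 - tc) +
        plane[cbind(r0 + 1, c0)] * tr * (1 - tc) +
        plane[cbind(r0, c0 + 1)] * (1 - tr) * tc +
        plane[cbind(r0 + 1, c0 + 1)] * tr * tc
      layers[[b]][gflat[ok]] <- v
    }
    mask[gflat[ok]] <- rframe$mask[cbind(round(fr[ok]), round(fc[ok]))]
  }
  offset[gflat[ok]] <- sqrt((fpix[ok, 1] - ctr[1])^2 +
                            (fpix[ok, 2] - ctr[2])^2)
  structure(list(layers = layers, mask = mask, center_offset = offset,
                 geometry = rframe$geometry, rmse = rmse),
            class = "aligned_frame")
}

#' Precedence score of a frame candidate at a pixel
#'
#' Lexicographic ordering key implementing the compositing preferences:
#' (1) lower observation angle, (2) longer focal length, (3) smaller offset
#' from the frame centre, (4) more recent acquisition (applied only under the
#' `"post"` epoch policy). Smaller keys win; exact ties are broken in
#' [composite()] by frame ID order.
#'
#' @param geometry An [acquisition_geometry].
#' @param pixel_offset Distance of the pixel from the frame centre (pixels).
#' @param epoch_policy `"pre"` or `"post"`.
#' @return Numeric vector key; compare with [precedence_wins()].
#' @export
precedence_score <- function(geometry, pixel_offset, epoch_policy = "pre") {
  c(angle = geometry$angle_deg,
    neg_focal = -geometry$focal_mm,
    offset = pixel_offset,
    neg_time = if (identical(epoch_policy, "post")) -geometry$timestamp else 0)
}

#' @rdname precedence_score
#' @param a,b Keys from [precedence_score()].
#' @return `precedence_wins`: `TRUE` if `a` strictly beats `b`.
#' @export
precedence_wins <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' Composite aligned frames into a mosaic
#'
#' Winner-takes-all compositing: at each grid pixel the valid candidate with
#' the best [precedence_score()] supplies all three bands (no blending, so no
#' pixel ever mixes radiances from two frames); the winning frame's ID is
#' recorded in the provenance layer. Ties are broken by frame ID sort order,
#' which also makes the result independent of the input list order.
#'
#' @param frames List of `aligned_frame` objects on a common grid.
#' @param epoch_policy `"pre"` or `"post"` (see [precedence_score()]).
#' @param crs,origin,res Grid georeferencing for the output.
#' @return An [alan_grid] with layers `r`, `g`, `b` and `provenance` (integer
#'   index into the sorted frame IDs, stored in attribute `frame_ids`); pixels
#'   with no valid frame are masked `off_scene`.
#' @export
composite <- function(frames, epoch_policy = "pre", crs = "EPSG:3035",
                      origin = c(0, 0), res = 500) {
  if (length(frames) == 0L) stop("empty frame list")
  d <- dim(frames[[1]]$layers$r)
  ids <- vapply(frames, function(f) f$geometry$frame_id, "")
  if (anyDuplicated(ids)) stop("duplicate frame IDs")
  ord <- order(ids)
  best <- list(angle = matrix(Inf, d[1], d[2]),
               neg_focal = matrix(Inf, d[1], d[2]),
               offset = matrix(Inf, d[1], d[2]),
               neg_time = matrix(Inf, d[1], d[2]))
  prov <- matrix(NA_integer_, d[1], d[2])
  out <- list(r = matrix(NA_real_, d[1], d[2]),
              g = matrix(NA_real_, d[1], d[2]),
              b = matrix(NA_real_, d[1], d[2]))
  reason <- matrix(mask_codes()[["off_scene"]], d[1], d[2])
  for (k in seq_along(ord)) {
    f <- frames[[ord[k]]]
    stopifnot(identical(dim(f$layers$r), d))
    g <- f$geometry
    key <- precedence_score(g, 0, epoch_policy)
    valid <- f$mask == 0L
    covered <- f$mask != mask_codes()[["off_scene"]] & !valid
    upd <- covered & reason == mask_codes()[["off_scene"]]
    reason[upd] <- f$mask[upd]
    win <- valid & (is.na(prov) |
      key[1] < best$angle |
      (key[1] == best$angle & (key[2] < best$neg_focal |
        (key[2] == best$neg_focal & (f$center_offset < best$offset |
          (f$center_offset == best$offset & key[4] < best$neg_time))))))
    if (!any(win)) next
    best$angle[win] <- key[1]
    best$neg_focal[win] <- key[2]
    best$offset[win] <- f$center_offset[win]
    best$neg_time[win] <- key[4]
    prov[win] <- k
    for (b in c("r", "g", "b")) out[[b]][win] <- f$layers[[b]][win]
  }
  # pixels no frame validly covers keep the first covering frame's reason
  # (cloud, saturated, ...), or off_scene if nothing covered them at all
  mask <- matrix(0L, d[1], d[2])
  mask[is.na(prov)] <- reason[is.na(prov)]
  g <- alan_grid(c(out, list(provenance = prov)), crs = crs, origin = origin,
                 res = res, mask = mask)
  attr(g, "frame_ids") <- ids[ord]
  g
}
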
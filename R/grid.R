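# georeferenced grid container and region polygons.
# Grids live on the 500-m analysis grid in an equal-area CRS (ETRS89-LAEA,
# EPSG:3035, by default). Layers are matrices (row 1 = northern edge); the
# mask matrix holds integer reason codes, 0 = valid.

#' Mask reason codes
#'
#' Integer codes used in grid masks. 0 is valid; nonzero pixels carry the
#' first reason that invalidated them and are excluded from all downstream
#' statistics.
#'
#' @return Named integer vector.
#' @export
mask_codes <- function() {
  c(valid = 0L, unlit = 1L, outlier = 2L, below_viirs_threshold = 3L,
    cloud = 4L, off_scene = 5L, saturated = 6L)
}

#' Georeferenced analysis grid
#'
#' Lightweight multi-layer raster: named list of equal-dimension matrices plus
#' CRS, affine transform (origin of the top-left corner and square pixel
#' size), and an integer mask of [mask_codes()].
#'
#' @param layers Named list of numeric matrices, identical dimensions.
#' @param crs CRS label, default `"EPSG:3035"`.
#' @param origin Map coordinates `c(x, y)` of the top-left corner.
#' @param res Pixel size in CRS units (default 500 m).
#' @param mask Optional integer matrix of reason codes; default all valid.
#' @return Object of class `alan_grid`.
#' @export
alan_grid <- function(layers, crs = "EPSG:3035", origin = c(0, 0), res = 500,
                      mask = NULL) {
  stopifnot(is.list(layers), length(layers) >= 1, !is.null(names(layers)))
  d <- dim(layers[[1]])
  for (l in layers) stopifnot(identical(dim(l), d))
  if (is.null(mask)) mask <- matrix(0L, d[1], d[2])
  stopifnot(identical(dim(mask), d))
  structure(list(layers = layers, crs = crs, origin = as.numeric(origin),
                 res = res, mask = mask),
            class = "alan_grid")
}

#' @export
print.alan_grid <- function(x, ...) {
  d <- dim(x$layers[[1]])
  cat(sprintf("<alan_grid %dx%d px, %g m, %s; layers: %s; %d/%d valid>\n",
              d[1], d[2], x$res, x$crs,
              paste(names(x$layers), collapse = ", "),
              sum(x$mask == 0L), length(x$mask)))
  invisible(x)
}

#' @export
dim.alan_grid <- function(x) dim(x$layers[[1]])

#' @export
plot.alan_grid <- function(x, layer = 1, ...) {
  m <- x$layers[[layer]]
  m[x$mask != 0L] <- NA
  graphics::image(t(m)[, nrow(m):1], axes = FALSE, asp = nrow(m) / ncol(m),
                  main = names(x$layers)[layer],
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Valid-pixel values of a grid layer
#'
#' @param grid An [alan_grid].
#' @param layer Layer name or index.
#' @return Numeric vector of values at mask-valid pixels.
#' @export
valid_values <- function(grid, layer = 1) {
  grid$layers[[layer]][grid$mask == 0L]
}

# map coordinates of pixel centres (vectorised over the whole grid)
pixel_centers <- function(grid) {
  d <- dim(grid)
  col <- rep(seq_len(d[2]), each = d[1])
  row <- rep(seq_len(d[1]), d[2])
  cbind(x = grid$origin[1] + (col - 0.5) * grid$res,
        y = grid$origin[2] - (row - 0.5) * grid$res)
}

check_congruent <- function(a, b) {
  if (!identical(dim(a), dim(b)) || !identical(a$crs, b$crs) ||
      any(abs(a$origin - b$origin) > 1e-6) || a$res != b$res)
    stop("grids are not co-registered (shape/CRS/transform mismatch); ",
         "explicit reprojection is required")
  invisible(TRUE)
}

#' Write / read a grid
#'
#' Lossless serialisation of an [alan_grid] including CRS, transform and mask
#' (RDS container; values kept at full precision).
#'
#' @param grid An [alan_grid].
#' @param path File path.
#' @return `write_grid` invisibly returns `path`; `read_grid` returns the grid.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "alan_grid"))
  if (is.null(grid$crs) || !nzchar(grid$crs)) stop("grid has no CRS declared")
  saveRDS(grid, path)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  g <- readRDS(path)
  if (!inherits(g, "alan_grid")) stop("not an alan_grid file: ", path)
  if (is.null(g$crs) || !nzchar(g$crs)) stop("grid file has no CRS declared")
  g
}

#' Region polygon set
#'
#' Named polygons (countries or species ranges) in the grid CRS.
#'
#' @param names Character vector of unique region IDs.
#' @param polygons List of closed 2-column coordinate matrices (x, y).
#' @param crs CRS label.
#' @param mode `"partition"` (disjoint cover) or `"ranges"` (may overlap).
#' @return Object of class `region_set`.
#' @export
region_set <- function(names, polygons, crs = "EPSG:3035",
                       mode = "partition") {
  stopifnot(length(names) == length(polygons), !anyDuplicated(names))
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    stopifnot(ncol(p) == 2, nrow(p) >= 3)
    if (any(p[1, ] != p[nrow(p), ])) p <- rbind(p, p[1, ])  # close ring
    if (polygon_area(p) < 0) p <- p[nrow(p):1, ]            # CCW orientation
    p
  })
  structure(list(names = as.character(names), polygons = polygons, crs = crs,
                 mode = mode),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set: %d %s regions, %s>\n", length(x$names), x$mode,
              x$crs))
  invisible(x)
}

#' @export
length.region_set <- function(x) length(x$names)

# signed shoelace area (positive = counterclockwise)
polygon_area <- function(p) {
  n <- nrow(p)
  sum(p[-n, 1] * p[-1, 2] - p[-1, 1] * p[-n, 2]) / 2
}

#' Region areas
#'
#' @param regions A [region_set].
#' @return Named numeric vector of polygon areas in CRS units squared.
#' @export
region_areas <- function(regions) {
  a <- vapply(regions$polygons, function(p) abs(polygon_area(p)), numeric(1))
  stats::setNames(a, regions$names)
}

#' Write / read regions as GeoJSON
#'
#' One Feature per region with its name as `properties$name` and the CRS
#' label as a top-level `crs` member.
#'
#' @param regions A [region_set].
#' @param path File path.
#' @return `write_regions_geojson` invisibly returns `path`;
#'   `read_regions_geojson` returns a [region_set].
#' @export
write_regions_geojson <- function(regions, path) {
  feats <- lapply(seq_along(regions$names), function(i) {
    p <- regions$polygons[[i]]
    list(type = "Feature",
         properties = list(name = regions$names[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(p)),
                                                   function(j) p[j, ]))))
  })
  obj <- list(type = "FeatureCollection", crs = regions$crs,
              mode = regions$mode, features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_regions_geojson
#' @export
read_regions_geojson <- function(path) {
  obj <- jsonlite::read_json(path)
  if (is.null(obj$crs)) stop("GeoJSON has no CRS declared")
  polys <- lapply(obj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    do.call(rbind, lapply(ring, function(pt) as.numeric(unlist(pt))))
  })
  nms <- vapply(obj$features, function(f) as.character(f$properties$name), "")
  region_set(nms, polys, crs = obj$crs,
             mode = if (is.null(obj$mode)) "partition" else obj$mode)
}
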
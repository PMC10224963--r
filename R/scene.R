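#' Construct a georeferenced scene
#'
#' A scene is the unit of detection and counting: a multi-band intensity
#' raster with square pixels, a world origin, and a CRS label. Band order is
#' conventionally R, G, B, NIR for WorldView-class sensors.
#'
#' Coordinate conventions used throughout the package:
#' * pixel indices `(row, col)` are 0-based; windows are half-open;
#' * the world coordinate of a pixel refers to its **center**;
#' * `origin` is the world coordinate of the top-left **corner** of the
#'   raster, with `y` decreasing as `row` increases (north-up).
#'
#' @param bands numeric array `height x width x n_bands` (at least 3 bands;
#'   4 expected: R, G, B, NIR), raw digital numbers.
#' @param pixel_size ground sample distance in meters per pixel (square).
#' @param origin numeric length-2 `(x, y)` world coordinate of the top-left
#'   corner, in meters.
#' @param crs_label text identifier of the coordinate reference system.
#' @param nodata optional sentinel value for missing pixels.
#' @param bit_depth sensor radiometric depth in bits; intensities are
#'   expected in `[0, 2^bit_depth - 1]`. Default 11 (WorldView-class).
#' @return an object of class `wd_scene`.
#' @export
new_scene <- function(bands, pixel_size, origin, crs_label = "local-meters",
                      nodata = NULL, bit_depth = 11L) {
  if (is.matrix(bands)) bands <- array(bands, c(dim(bands), 1L))
  if (length(dim(bands)) != 3L) stopf("`bands` must be a 3-D array (H, W, B)")
  if (dim(bands)[3] < 3L)
    stopf("a scene needs >= 3 bands, got %d", dim(bands)[3])
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stopf("`pixel_size` must be a single positive number")
  if (length(origin) != 2L) stopf("`origin` must be (x, y)")
  structure(
    list(bands = bands, pixel_size = as.numeric(pixel_size),
         origin = as.numeric(origin), crs_label = crs_label,
         nodata = nodata, bit_depth = as.integer(bit_depth)),
    class = "wd_scene")
}

#' @export
print.wd_scene <- function(x, ...) {
  d <- dim(x$bands)
  cat(sprintf("<wd_scene> %d x %d px, %d bands, %.2f m/px, origin (%.1f, %.1f), crs '%s'\n",
              d[1], d[2], d[3], x$pixel_size, x$origin[1], x$origin[2],
              x$crs_label))
  invisible(x)
}

#' @rdname new_scene
#' @param x object to test
#' @export
is_scene <- function(x) inherits(x, "wd_scene")

scene_dim <- function(scene) dim(scene$bands)[1:2]

#' Geotransform of a scene
#'
#' The minimal geotransform used by the package: origin of the top-left
#' corner plus pixel size. Patches extracted from a scene carry their own.
#'
#' @param scene a `wd_scene`, or a list with `origin` and `pixel_size`.
#' @return list with `origin` and `pixel_size`.
#' @export
geotransform <- function(scene) {
  list(origin = scene$origin, pixel_size = scene$pixel_size)
}

#' Convert between pixel and world coordinates
#'
#' `pixel_to_world()` maps 0-based (row, col) pixel-center coordinates to
#' world (x, y); `world_to_pixel()` is its exact inverse and returns
#' fractional pixel coordinates (integers for points exactly on pixel
#' centers). The two round-trip exactly for integer pixel centers.
#'
#' @param gt a scene or geotransform (list with `origin`, `pixel_size`).
#' @param row,col 0-based pixel coordinates (vectors, may be fractional).
#' @param x,y world coordinates in meters (vectors).
#' @return a data.frame with columns `x`,`y` (or `row`,`col`).
#' @export
pixel_to_world <- function(gt, row, col) {
  px <- gt$pixel_size
  data.frame(x = gt$origin[1] + (col + 0.5) * px,
             y = gt$origin[2] - (row + 0.5) * px)
}

#' @rdname pixel_to_world
#' @export
world_to_pixel <- function(gt, x, y) {
  px <- gt$pixel_size
  data.frame(row = (gt$origin[2] - y) / px - 0.5,
             col = (x - gt$origin[1]) / px - 0.5)
}

#' Read and write scenes
#'
#' Rasters are stored as multi-sample float TIFF with two plain-text
#' sidecars: an ESRI world file (`.tfw`) holding the geotransform and a
#' JSON file (`.meta.json`) holding the CRS label, nodata value and sensor
#' bit depth. `load_scene()` refuses files without a world file, since a
#' scene without a geotransform cannot be georeferenced.
#'
#' @param path path to a `.tif` file.
#' @param scene a `wd_scene`.
#' @param require_bands if non-NULL, error unless the file has at least this
#'   many bands (the pipeline expects 4: R, G, B, NIR).
#' @return `load_scene()` returns a `wd_scene`; `write_scene()` returns
#'   `path` invisibly.
#' @export
load_scene <- function(path, require_bands = NULL) {
  if (!file.exists(path)) stopf("raster file not found: %s", path)
  # multi-band files trip a harmless ExtraSamples note in libtiff
  img <- suppressWarnings(tiff::readTIFF(path, as.is = FALSE))
  if (is.matrix(img)) img <- array(img, c(dim(img), 1L))
  tfw <- sub("\\.tiff?$", ".tfw", path)
  if (!file.exists(tfw))
    stopf("missing geotransform: no world file beside %s", path)
  w <- as.numeric(readLines(tfw))
  if (length(w) != 6 || w[1] <= 0) stopf("malformed world file: %s", tfw)
  # world file stores the center of the top-left pixel
  px <- w[1]
  origin <- c(w[5] - px / 2, w[6] + px / 2)
  meta_path <- sub("\\.tiff?$", ".meta.json", path)
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  bit_depth <- meta$bit_depth %||% 11L
  scene <- new_scene(img * (2^bit_depth - 1), pixel_size = px, origin = origin,
                     crs_label = meta$crs_label %||% "local-meters",
                     nodata = meta$nodata, bit_depth = bit_depth)
  if (!is.null(require_bands) && dim(scene$bands)[3] < require_bands)
    stopf("%s has %d bands; %d required", path, dim(scene$bands)[3],
          require_bands)
  scene
}

#' @rdname load_scene
#' @export
write_scene <- function(scene, path) {
  stopifnot(is_scene(scene))
  maxv <- 2^scene$bit_depth - 1
  tiff::writeTIFF(scene$bands / maxv, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  px <- scene$pixel_size
  writeLines(format(c(px, 0, 0, -px,
                      scene$origin[1] + px / 2, scene$origin[2] - px / 2),
                    digits = 17),
             sub("\\.tiff?$", ".tfw", path))
  jsonlite::write_json(
    list(crs_label = scene$crs_label, nodata = scene$nodata,
         bit_depth = scene$bit_depth),
    sub("\\.tiff?$", ".meta.json", path), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Build the tiling grid of a scene
#'
#' Tiles the scene into non-overlapping cells of `patch_px` x `patch_px`
#' pixels, anchored at the scene's top-left corner. At 0.5 m resolution a
#' 336-pixel cell covers 168 m of ground; at 0.45 m, 151.2 m. Border cells
#' narrower than `patch_px` are kept but flagged `full = FALSE`; they are
#' zero-padded for inference and excluded from training sampling.
#'
#' @param scene a `wd_scene`.
#' @param patch_px cell edge in pixels (default 336).
#' @return data.frame with one row per cell: `row_index`, `col_index`
#'   (0-based cell indices), `row0`, `col0`, `height`, `width` (half-open
#'   pixel window), `full` (covers a complete patch), `ground_extent`
#'   (meters, of a full cell).
#' @export
build_grid <- function(scene, patch_px = 336L) {
  stopifnot(is_scene(scene))
  d <- scene_dim(scene)
  if (any(d < patch_px))
    stopf("scene (%d x %d px) is smaller than one %d-px patch", d[1], d[2],
          patch_px)
  nr <- ceiling(d[1] / patch_px); nc <- ceiling(d[2] / patch_px)
  g <- expand.grid(row_index = seq_len(nr) - 1L, col_index = seq_len(nc) - 1L)
  g$row0 <- g$row_index * patch_px
  g$col0 <- g$col_index * patch_px
  g$height <- pmin(patch_px, d[1] - g$row0)
  g$width <- pmin(patch_px, d[2] - g$col0)
  g$full <- g$height == patch_px & g$width == patch_px
  g$ground_extent <- patch_px * scene$pixel_size
  g[order(g$row_index, g$col_index), , drop = FALSE]
}

#' Extract one grid cell as a patch
#'
#' Returns the pixel window of `cell` as a scene of its own, carrying the
#' offset geotransform. Partial border cells are zero-padded to
#' `patch_px` x `patch_px` when `pad = TRUE`; the valid window size is kept
#' in attributes `valid_height`/`valid_width` so predictions can be cropped
#' back.
#'
#' @param scene a `wd_scene`.
#' @param cell one row of [build_grid()]'s output (data.frame or list with
#'   `row0`, `col0`, `height`, `width`).
#' @param pad zero-pad partial cells to the full patch size.
#' @param patch_px patch edge used when padding.
#' @return a `wd_scene` patch.
#' @export
extract_patch <- function(scene, cell, pad = FALSE, patch_px = 336L) {
  stopifnot(is_scene(scene))
  d <- scene_dim(scene)
  r0 <- cell$row0; c0 <- cell$col0; h <- cell$height; w <- cell$width
  if (r0 < 0 || c0 < 0 || r0 + h > d[1] || c0 + w > d[2])
    stopf("cell window [%d,%d)+%dx%d is outside the %d x %d scene",
          r0, c0, h, w, d[1], d[2])
  block <- scene$bands[(r0 + 1):(r0 + h), (c0 + 1):(c0 + w), , drop = FALSE]
  vh <- h; vw <- w
  if (pad && (h < patch_px || w < patch_px)) {
    padded <- array(0, c(patch_px, patch_px, dim(block)[3]))
    padded[1:h, 1:w, ] <- block
    block <- padded
  }
  p <- new_scene(block, pixel_size = scene$pixel_size,
                 origin = c(scene$origin[1] + c0 * scene$pixel_size,
                            scene$origin[2] - r0 * scene$pixel_size),
                 crs_label = scene$crs_label, nodata = scene$nodata,
                 bit_depth = scene$bit_depth)
  attr(p, "valid_height") <- vh
  attr(p, "valid_width") <- vw
  p
}

#' Export a grid as GeoJSON polygons
#'
#' Writes each grid cell as a Polygon feature (corner coordinates in world
#' units) with its indices and `full` flag as properties, for visual
#' inspection in any GIS viewer.
#'
#' @param grid output of [build_grid()].
#' @param scene the gridded `wd_scene`.
#' @param path output `.geojson` path.
#' @export
write_grid_geojson <- function(grid, scene, path) {
  px <- scene$pixel_size
  feats <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    x0 <- scene$origin[1] + g$col0 * px
    y0 <- scene$origin[2] - g$row0 * px
    x1 <- x0 + g$width * px
    y1 <- y0 - g$height * px
    ring <- list(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0))
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = list(row_index = g$row_index,
                           col_index = g$col_index, full = g$full))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Normalize a patch for the network
#'
#' Per-band division by the sensor bit-depth maximum (`2^bit_depth - 1`,
#' default 2047 for 11-bit WorldView-class data), a fixed global scaling
#' that keeps training and inference consistent across scenes.
#'
#' @param patch a `wd_scene` (or bare array).
#' @param bit_depth override of the sensor bit depth.
#' @return numeric array in `[0, 1]`.
#' @export
normalize_patch <- function(patch, bit_depth = NULL) {
  if (is_scene(patch)) {
    bit_depth <- bit_depth %||% patch$bit_depth
    arr <- patch$bands
  } else {
    bit_depth <- bit_depth %||% 11L
    arr <- patch
  }
  pmin(pmax(arr / (2^bit_depth - 1), 0), 1)
}
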
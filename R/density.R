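#' Point-density hotspot raster
#'
#' Neighborhood point density on a regular grid: the value of each cell is
#' the number of detection points within `radius` of the cell center,
#' divided by the neighborhood area, expressed in animals per square
#' kilometre. Defaults (100 m cells, 500 m radius) match the scale at
#' which dry-season herd aggregations are usually mapped.
#'
#' @param points a `wd_points`.
#' @param extent numeric `(xmin, ymin, xmax, ymax)` in meters.
#' @param cell_size cell edge in meters (default 100).
#' @param radius neighborhood radius in meters (default 500; must be at
#'   least `cell_size / 2`).
#' @return list of class `wd_density`: `values` (matrix, rows north to
#'   south), `cell_size`, `radius`, `origin` (top-left corner of the grid).
#' @export
point_density <- function(points, extent, cell_size = 100, radius = 500) {
  if (length(extent) != 4 || extent[3] <= extent[1] || extent[4] <= extent[2])
    stopf("extent must be (xmin, ymin, xmax, ymax) with positive area")
  if (radius < cell_size / 2) stopf("radius must be >= cell_size / 2")
  nx <- ceiling((extent[3] - extent[1]) / cell_size)
  ny <- ceiling((extent[4] - extent[2]) / cell_size)
  cx <- extent[1] + (seq_len(nx) - 0.5) * cell_size
  cy <- extent[4] - (seq_len(ny) - 0.5) * cell_size
  vals <- matrix(0, ny, nx)
  area_km2 <- pi * (radius / 1000)^2
  if (nrow(points)) {
    r2 <- radius^2
    for (i in seq_len(ny)) {
      dy2 <- (points$y - cy[i])^2
      near <- dy2 <= r2
      if (!any(near)) next
      px <- points$x[near]; dy2 <- dy2[near]
      # vectorized over cells of this row
      cnt <- vapply(cx, function(x0) sum((px - x0)^2 + dy2 <= r2), numeric(1))
      vals[i, ] <- cnt / area_km2
    }
  }
  structure(list(values = vals, cell_size = cell_size, radius = radius,
                 origin = c(extent[1], extent[4])),
            class = "wd_density")
}

#' @export
print.wd_density <- function(x, ...) {
  cat(sprintf("<wd_density> %d x %d cells of %g m, radius %g m, max %.1f /km^2\n",
              nrow(x$values), ncol(x$values), x$cell_size, x$radius,
              max(x$values)))
  invisible(x)
}

#' Count-per-square-kilometre histogram
#'
#' Partitions the extent into square cells (1 km^2 by default) anchored at
#' the extent's top-left corner, counts the points per cell (half-open
#' cells, so every in-extent point lands in exactly one) and tabulates the
#' per-cell counts. The total histogram mass times counts equals the
#' number of points inside the extent exactly.
#'
#' @param points a `wd_points`.
#' @param extent numeric `(xmin, ymin, xmax, ymax)` in meters.
#' @param bin_cell cell edge in meters (default 1000, i.e. 1 km^2 cells).
#' @return data.frame with columns `count` (animals per cell) and
#'   `n_cells` (cells with that count), plus attribute `n_points` (points
#'   inside the extent).
#' @export
density_histogram <- function(points, extent, bin_cell = 1000) {
  if (length(extent) != 4 || extent[3] <= extent[1] || extent[4] <= extent[2])
    stopf("extent must be (xmin, ymin, xmax, ymax) with positive area")
  nx <- ceiling((extent[3] - extent[1]) / bin_cell)
  ny <- ceiling((extent[4] - extent[2]) / bin_cell)
  ix <- floor((points$x - extent[1]) / bin_cell)
  iy <- floor((extent[4] - points$y) / bin_cell)
  inside <- ix >= 0 & ix < nx & iy >= 0 & iy < ny
  cell_id <- iy[inside] * nx + ix[inside]
  counts <- rep(0L, nx * ny)
  if (length(cell_id)) {
    tb <- table(cell_id)
    counts[as.integer(names(tb)) + 1L] <- as.integer(tb)
  }
  tab <- table(counts)
  out <- data.frame(count = as.integer(names(tab)),
                    n_cells = as.integer(tab))
  attr(out, "n_points") <- sum(inside)
  out
}

#' Write a density raster
#'
#' Single-band float TIFF with world-file sidecar, values in animals per
#' square kilometre.
#'
#' @param dmap a `wd_density`.
#' @param path output `.tif` path.
#' @export
write_density <- function(dmap, path) {
  mx <- max(dmap$values, 1)
  tiff::writeTIFF(dmap$values / mx, path, bits.per.sample = 32L,
                  compression = "none")
  px <- dmap$cell_size
  writeLines(format(c(px, 0, 0, -px, dmap$origin[1] + px / 2,
                      dmap$origin[2] - px / 2), digits = 17),
             sub("\\.tiff?$", ".tfw", path))
  jsonlite::write_json(list(scale_max = mx, units = "animals_per_km2"),
                       sub("\\.tiff?$", ".meta.json", path),
                       auto_unbox = TRUE)
  invisible(path)
}
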
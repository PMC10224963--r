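test_that("scene round-trips through TIFF with geotransform intact", {
  sim <- generate_scene(scene_spec(width_px = 64, height_px = 48,
                                   n_animals = 5, min_sep_px = 4, seed = 3))
  path <- file.path(tempdir(), "rt.tif")
  write_scene(sim$scene, path)
  back <- load_scene(path)
  expect_equal(dim(back$bands), dim(sim$scene$bands))
  # float32 storage: identical to within single-precision DN resolution
  expect_lt(max(abs(back$bands - sim$scene$bands)), 1e-3)
  expect_equal(back$pixel_size, sim$scene$pixel_size)
  expect_equal(back$origin, sim$scene$origin)
  expect_equal(back$crs_label, "synthetic-meters")
})

test_that("loading rejects missing geotransform and insufficient bands", {
  s <- make_toy_scene(bands = 3)
  path <- file.path(tempdir(), "b3.tif")
  write_scene(s, path)
  expect_error(load_scene(path, require_bands = 4), "3 bands")
  file.remove(sub("\\.tif$", ".tfw", path))
  expect_error(load_scene(path), "geotransform")
  expect_error(load_scene(file.path(tempdir(), "nope.tif")), "not found")
})

test_that("pixel/world conversion round-trips exactly on pixel centers", {
  gt <- list(origin = c(-250, 1000), pixel_size = 0.45)
  rc <- expand.grid(row = c(0L, 1L, 17L, 335L), col = c(0L, 2L, 100L))
  w <- pixel_to_world(gt, rc$row, rc$col)
  back <- world_to_pixel(gt, w$x, w$y)
  expect_equal(back$row, as.numeric(rc$row))
  expect_equal(back$col, as.numeric(rc$col))
})

test_that("grid cells tile the scene with correct ground extent", {
  s <- make_toy_scene(h = 672, w = 672, pixel_size = 0.5)
  g <- build_grid(s, 336L)
  expect_equal(nrow(g), 4L)
  expect_true(all(g$full))
  expect_equal(unique(g$ground_extent), 168)        # 336 x 0.5 m
  g45 <- build_grid(new_scene(s$bands, 0.45, c(0, 0)), 336L)
  expect_equal(unique(g45$ground_extent), 151.2)    # 336 x 0.45 m
  # windows are disjoint and cover every pixel
  cover <- matrix(0L, 672, 672)
  for (i in seq_len(nrow(g)))
    cover[g$row0[i] + 1:g$height[i], g$col0[i] + 1:g$width[i]] <-
      cover[g$row0[i] + 1:g$height[i], g$col0[i] + 1:g$width[i]] + 1L
  expect_true(all(cover == 1L))
  expect_error(build_grid(make_toy_scene(h = 100, w = 100), 336L), "smaller")
})

test_that("partial border cells are flagged and zero-padded on extraction", {
  s <- make_toy_scene(h = 150, w = 100)
  g <- build_grid(s, 96L)
  expect_equal(sum(g$full), 1L)
  border <- g[g$row_index == 1 & g$col_index == 0, ]  # 54 x 96 strip
  p <- extract_patch(s, border, pad = TRUE, patch_px = 96L)
  expect_equal(dim(p$bands)[1:2], c(96L, 96L))
  expect_equal(attr(p, "valid_height"), border$height)
  expect_true(all(p$bands[(border$height + 1):96, , ] == 0))
})

test_that("patch extraction copies the window and offsets the origin", {
  s <- make_toy_scene(h = 192, w = 192)
  g <- build_grid(s, 96L)
  p <- extract_patch(s, g[1, ])
  expect_identical(p$bands, s$bands[1:96, 1:96, , drop = FALSE])
  p2 <- extract_patch(s, g[g$row_index == 1 & g$col_index == 1, ])
  expect_equal(p2$origin,
               c(s$origin[1] + 96 * 0.5, s$origin[2] - 96 * 0.5))
  expect_identical(p2$bands, extract_patch(s, g[4, ])$bands)
  expect_error(extract_patch(s, list(row0 = 100L, col0 = 100L,
                                     height = 96L, width = 96L)),
               "outside")
  # full-cell patches reconstruct the scene exactly
  rec <- array(0, dim(s$bands))
  for (i in seq_len(nrow(g))) {
    pi <- extract_patch(s, g[i, ])
    rec[g$row0[i] + 1:96, g$col0[i] + 1:96, ] <- pi$bands
  }
  expect_identical(rec, s$bands)
})

test_that("grids export as GeoJSON polygons with cell properties", {
  s <- make_toy_scene(h = 150, w = 100)
  g <- build_grid(s, 96L)
  path <- file.path(tempdir(), "grid.geojson")
  write_grid_geojson(g, s, path)
  gj <- jsonlite::read_json(path)
  expect_length(gj$features, nrow(g))
  f1 <- gj$features[[1]]
  expect_equal(f1$geometry$type, "Polygon")
  ring <- f1$geometry$coordinates[[1]]
  expect_length(ring, 5L)                     # closed ring
  expect_equal(unlist(ring[[1]]), unlist(ring[[5]]))
  expect_false(is.null(f1$properties$full))
})

test_that("point sets round-trip through CSV and GeoJSON", {
  pts <- new_points(c(1.5, 2.5, 100), c(-3, 0.25, 42),
                    score = c(0.9, 0.5, 1), source_tag = "prediction")
  for (ext in c("p.csv", "p.geojson")) {
    path <- file.path(tempdir(), ext)
    write_points(pts, path)
    back <- read_points(path)
    expect_equal(back$x, pts$x)
    expect_equal(back$y, pts$y)
    expect_equal(back$score, pts$score)
    expect_equal(attr(back, "source_tag"), "prediction")
  }
  empty <- new_points(source_tag = "consensus")
  path <- file.path(tempdir(), "e.geojson")
  write_points(empty, path)
  expect_equal(nrow(read_points(path)), 0L)
})
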
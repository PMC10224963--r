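test_that("scene generation is seeded and bit-reproducible", {
  spec <- scene_spec(width_px = 96, height_px = 96, n_animals = 20, seed = 5)
  a <- generate_scene(spec)
  b <- generate_scene(spec)
  expect_identical(a$scene$bands, b$scene$bands)
  expect_identical(as.data.frame(a$truth), as.data.frame(b$truth))
  c <- generate_scene(scene_spec(width_px = 96, height_px = 96,
                                 n_animals = 20, seed = 6))
  expect_false(identical(a$scene$bands, c$scene$bands))
})

test_that("ground truth count always equals the requested n_animals", {
  for (agg in c("scattered", "linear", "clustered")) {
    for (n in c(0L, 1L, 40L)) {
      sim <- generate_scene(scene_spec(width_px = 128, height_px = 128,
                                       n_animals = n, aggregation = agg,
                                       seed = n + 3))
      expect_equal(nrow(sim$truth), n)
      expect_true(all(points_in_scene(sim$truth, sim$scene)))
    }
  }
  expect_error(generate_scene(scene_spec(width_px = 48, height_px = 48,
                                         n_animals = 500, seed = 1)),
               "cannot place")
})

test_that("animals are darker than their local background by a clear margin", {
  sim <- generate_scene(scene_spec(width_px = 96, height_px = 96,
                                   n_animals = 15, seed = 9,
                                   confusers = c(bush = 0, mound_shadow = 0,
                                                 road = 0, river = 0)))
  red <- sim$scene$bands[, , 1]
  px <- world_to_pixel(geotransform(sim$scene), sim$truth$x, sim$truth$y)
  centers <- red[cbind(round(px$row) + 1, round(px$col) + 1)]
  expect_lt(max(centers), 0.75 * median(red))
})

test_that("clustered placement concentrates animals around few parents", {
  sim_c <- generate_scene(scene_spec(width_px = 256, height_px = 256,
                                     n_animals = 60,
                                     aggregation = "clustered",
                                     cluster_parents = 3, cluster_spread = 4,
                                     seed = 13))
  sim_s <- generate_scene(scene_spec(width_px = 256, height_px = 256,
                                     n_animals = 60, seed = 13))
  nn_dist <- function(p) {
    d <- as.matrix(dist(cbind(p$x, p$y)))
    diag(d) <- Inf
    mean(apply(d, 1, min))
  }
  expect_lt(nn_dist(sim_c$truth), nn_dist(sim_s$truth))
})

test_that("reference pairs share static objects and differ only at animals", {
  spec <- scene_spec(width_px = 96, height_px = 96, n_animals = 12, seed = 4,
                     confusers = c(bush = 3, mound_shadow = 2, road = 1,
                                   river = 0))
  pair <- generate_reference_pair(spec)
  diff <- abs(pair$scene_a$bands - pair$scene_b$bands)
  changed <- which(apply(diff, c(1, 2), max) > 1e-9, arr.ind = TRUE)
  expect_gt(nrow(changed), 0)
  # every changed pixel is within an animal footprint (<= 3 px of a truth)
  px <- world_to_pixel(geotransform(pair$scene_a), pair$truth$x,
                       pair$truth$y)
  for (i in seq_len(nrow(changed))) {
    d <- sqrt((px$row - (changed[i, 1] - 1))^2 +
                (px$col - (changed[i, 2] - 1))^2)
    expect_lte(min(d), 3)
  }
  # the pair is identical away from animals (confusers are static)
  expect_lt(nrow(changed), 12 * 26)
})

test_that("scene specs round-trip through YAML", {
  spec <- scene_spec(width_px = 64, height_px = 64, n_animals = 9,
                     aggregation = "clustered", cluster_spread = 7,
                     seed = 12)
  path <- file.path(tempdir(), "spec.yaml")
  write_scene_spec(spec, path)
  back <- read_scene_spec(path)
  expect_equal(back[names(back) != "confusers"],
               spec[names(spec) != "confusers"], ignore_attr = TRUE)
  expect_equal(unlist(back$confusers), unlist(spec$confusers))
  # the round-tripped spec regenerates the identical scene
  expect_identical(generate_scene(back)$scene$bands,
                   generate_scene(spec)$scene$bands)
})

test_that("oracle probability maps drive exact recovery at zero noise", {
  sim <- generate_scene(scene_spec(width_px = 128, height_px = 128,
                                   n_animals = 25, seed = 31))
  gt <- geotransform(sim$scene)
  p <- generate_oracle_probmap(sim$truth, gt, c(128, 128), noise_level = 0)
  expect_setequal(unique(as.vector(p)), c(0, 1))
  det <- detect_from_probmap(p, gt, detect_config())
  m <- match_points(det, sim$truth, matching_radius(0.5))
  mt <- compute_metrics(m)
  expect_equal(mt$f1, 1.0)
  # noisy map keeps blocks above and background below 0.5
  set.seed(2)
  pn <- generate_oracle_probmap(sim$truth, gt, c(128, 128),
                                noise_level = 0.3)
  expect_true(all(pn >= 0 & pn <= 1))
  detn <- detect_from_probmap(pn, gt, detect_config())
  expect_equal(compute_metrics(match_points(detn, sim$truth,
                                            matching_radius(0.5)))$f1, 1.0)
  expect_error(generate_oracle_probmap(sim$truth, gt, c(128, 128), 0.6),
               "noise_level")
})
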
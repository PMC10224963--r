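test_that("binarization uses an inclusive threshold and is monotone", {
  p <- matrix(c(0, 0.25, 0.5, 0.75, 1, 0.49), 2, 3)
  m <- binarize(p, 0.5)
  expect_equal(as.vector(m), as.integer(c(0, 0, 1, 1, 1, 0)))
  expect_equal(sum(binarize(p, 1e-9)), 5L)  # only exact zero stays off
  expect_equal(sum(binarize(matrix(0, 4, 4), 0.5)), 0L)
  # raising the threshold never adds positive pixels
  set.seed(2)
  q <- matrix(runif(400), 20, 20)
  counts <- sapply(seq(0.1, 0.9, 0.1), function(th) sum(binarize(q, th)))
  expect_true(all(diff(counts) <= 0))
})

test_that("segment labeling distinguishes 4- and 8-connectivity", {
  m <- matrix(0L, 5, 5)
  m[2, 2] <- 1L; m[3, 3] <- 1L      # diagonal touch
  expect_length(label_segments(m, 8L), 1L)
  expect_length(label_segments(m, 4L), 2L)
  expect_length(label_segments(matrix(0L, 5, 5)), 0L)
  # segments come back as 0-based pixel lists
  seg <- label_segments(m, 8L)[[1]]
  expect_setequal(paste(seg$row, seg$col), c("1 1", "2 2"))
  # a scattered random mask: total pixels conserved
  set.seed(8)
  mm <- matrix(rbinom(900, 1, 0.2), 30, 30)
  segs <- label_segments(mm, 8L)
  expect_equal(sum(vapply(segs, nrow, integer(1))), sum(mm))
})

test_that("ceiling rule converts segment sizes to individual counts", {
  expect_equal(clusters_for_segment(9L), 1L)
  expect_equal(clusters_for_segment(10L), 2L)
  expect_equal(clusters_for_segment(1L), 1L)
  expect_equal(clusters_for_segment(c(18L, 19L, 27L)), c(2L, 3L, 3L))
  expect_equal(clusters_for_segment(5L, object_size_px = 4L), 2L)
  expect_error(clusters_for_segment(0L), "non-empty")
})

test_that("k-means splitting returns centroids inside the bounding box", {
  # symmetric 3x3 block: centroid is the center pixel
  block <- expand.grid(row = 9:11, col = 4:6)
  ctr <- split_segment(block, 1)
  expect_equal(c(ctr$row, ctr$col), c(10, 5))
  # single pixel
  expect_equal(unlist(split_segment(data.frame(row = 3, col = 7), 1)),
               c(row = 3, col = 7))
  # k = n returns the pixels themselves
  two <- data.frame(row = c(0, 5), col = c(0, 0))
  s <- split_segment(two, 2, seed = 1)
  expect_setequal(s$row, c(0, 5))
  expect_error(split_segment(two, 3), "cannot split")
  # deterministic under seed
  set.seed(31)
  seg <- label_segments(binarize(matrix(runif(144), 12, 12), 0.35), 8L)[[1]]
  k <- min(3, nrow(seg))
  expect_identical(split_segment(seg, k, seed = 99),
                   split_segment(seg, k, seed = 99))
})

test_that("best-of-restarts k-means matches the exhaustive optimum on small segments", {
  set.seed(17)
  n_checked <- 0
  for (rep in 1:40) {
    mm <- matrix(rbinom(100, 1, 0.35), 10, 10)
    segs <- label_segments(mm, 8L)
    for (seg in segs) {
      n <- nrow(seg)
      if (n < 4 || n > 11) next
      for (k in 2:3) {
        if (k >= n) next
        ctr <- split_segment(seg, k, seed = rep)
        ss <- split_ss(seg, ctr)
        best <- exhaustive_kmeans_ss(cbind(seg$row, seg$col), k)
        expect_lt(abs(ss - best), 1e-8)
        n_checked <- n_checked + 1
      }
    }
    if (n_checked > 25) break
  }
  expect_gt(n_checked, 10)
})

test_that("probability-map detection recovers isolated and merged animals", {
  gt <- list(origin = c(0, 50), pixel_size = 0.5)
  # two isolated 3x3 animals
  w <- pixel_to_world(gt, c(10, 30), c(10, 30))
  truth <- new_points(w$x, w$y)
  p <- generate_oracle_probmap(truth, gt, c(100, 100))
  det <- detect_from_probmap(p, gt, detect_config())
  expect_equal(nrow(det), 2L)
  m <- match_points(det, truth, matching_radius(0.5))
  expect_equal(nrow(m$tp_pairs), 2L)
  # two animals one pixel apart merge into ~15-18 px -> 2 points
  w2 <- pixel_to_world(gt, c(50, 50), c(50, 54))
  p2 <- generate_oracle_probmap(new_points(w2$x, w2$y), gt, c(100, 100))
  det2 <- detect_from_probmap(p2, gt, detect_config())
  expect_equal(nrow(det2), 2L)
  # empty map
  expect_equal(nrow(detect_from_probmap(matrix(0, 50, 50), gt,
                                        detect_config())), 0L)
})

test_that("emitted points equal the sum of per-segment ceiling counts", {
  set.seed(12)
  gt <- list(origin = c(0, 64), pixel_size = 1)
  for (rep in 1:20) {
    p <- matrix(runif(64 * 64), 64, 64)^2
    det <- detect_from_probmap(p, gt, detect_config(prob_threshold = 0.7))
    segs <- label_segments(binarize(p, 0.7), 8L)
    expected <- sum(vapply(segs, function(s)
      clusters_for_segment(nrow(s)), integer(1)))
    expect_equal(nrow(det), expected)
  }
})

test_that("scene-level detection on an oracle map recovers every animal", {
  sim <- generate_scene(scene_spec(width_px = 144, height_px = 120,
                                   n_animals = 30, seed = 77))
  p <- generate_oracle_probmap(sim$truth, geotransform(sim$scene),
                               dim(sim$scene$bands)[1:2])
  det <- detect_scene(p, sim$scene)
  m <- match_points(det, sim$truth, matching_radius(0.5))
  expect_equal(nrow(m$tp_pairs), 30L)
  expect_equal(length(m$fp), 0L)
  # a probability source given as a function goes through the tiling path
  det2 <- detect_scene(function(patch) matrix(0, dim(patch)[1],
                                              dim(patch)[2]),
                       sim$scene, patch_px = 96L)
  expect_equal(nrow(det2), 0L)
})

test_that("an animal straddling a tile seam may split into two detections", {
  gt <- list(origin = c(0, 48), pixel_size = 0.5)
  # 3x3 block centered on the seam column of a 96-px overlap-free tiling
  w <- pixel_to_world(gt, 50, 95)
  sc <- new_scene(array(500, c(96, 192, 4)), 0.5, c(0, 48))
  pm <- generate_oracle_probmap(new_points(w$x, w$y), gt, c(96, 192))
  grid <- build_grid(sc, 96L)
  pts <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    cell <- grid[i, ]
    sub <- pm[cell$row0 + 1:cell$height, cell$col0 + 1:cell$width,
              drop = FALSE]
    p <- extract_patch(sc, cell, pad = TRUE, patch_px = 96L)
    as.data.frame(detect_from_probmap(sub, geotransform(p),
                                      detect_config()))
  }))
  # the 3x3 block is cut into a 3x1 and a 3x2 piece: one point each
  expect_equal(nrow(pts), 2L)
  dists <- sqrt((pts$x - w$x)^2 + (pts$y - w$y)^2)
  expect_true(all(dists <= 1))   # both pieces stay near the true animal
})

test_that("census confidence interval uses the t quantile", {
  est <- count_with_ci(c(100, 100, 100))
  expect_equal(est$mean_count, 100)
  expect_equal(est$half_width, 0)
  est2 <- count_with_ci(1:5)
  expect_equal(est2$mean_count, 3)
  expect_equal(est2$half_width, qt(0.975, 4) * sd(1:5) / sqrt(5))
  expect_equal(round(est2$half_width, 3), 1.963)
  # the normal approximation is narrower at n = 5
  expect_lt(count_with_ci(1:5, normal = TRUE)$half_width, est2$half_width)
  expect_error(count_with_ci(42), ">= 2")
})
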
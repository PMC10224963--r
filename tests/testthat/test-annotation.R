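test_that("majority voting keeps points marked by enough observers", {
  # four observers agree on one animal, one observer hallucinates another
  base <- c(10, 20)
  obs <- lapply(1:4, function(i)
    new_points(base[1] + 0.1 * i, base[2] - 0.1 * i,
               source_tag = paste0("observer-", i)))
  obs[[1]] <- rbind(obs[[1]], data.frame(x = 50, y = 50))
  class(obs[[1]]) <- c("wd_points", "data.frame")
  cons <- fuse_annotations(obs, radius = 1, min_votes = 3)
  expect_equal(nrow(cons), 1L)
  expect_equal(cons$x, mean(base[1] + 0.1 * (1:4)))
  expect_equal(attr(cons, "n_dropped"), 1L)
  expect_equal(attr(cons, "source_tag"), "consensus")
})

test_that("fusion is invariant to observer order and validates inputs", {
  set.seed(5)
  obs <- lapply(1:4, function(i) {
    n <- 6
    new_points(round(runif(n, 0, 100), 1), round(runif(n, 0, 100), 1))
  })
  a <- fuse_annotations(obs, radius = 5, min_votes = 2)
  b <- fuse_annotations(rev(obs), radius = 5, min_votes = 2)
  expect_equal(a[order(a$x, a$y), ], b[order(b$x, b$y), ],
               ignore_attr = TRUE)
  expect_error(fuse_annotations(obs, radius = 5, min_votes = 5),
               "exceeds")
  expect_error(fuse_annotations(obs[1], radius = 5), ">= 2")
  empty <- lapply(1:3, function(i) new_points())
  expect_equal(nrow(fuse_annotations(empty, radius = 1)), 0L)
})

test_that("rasterization paints clipped 3x3 blocks and merges overlaps", {
  gt <- list(origin = c(0, 50), pixel_size = 1)
  interior <- pixel_to_world(gt, 10, 10)
  m <- rasterize_points(new_points(interior$x, interior$y), gt, c(50, 50))
  expect_equal(sum(m), 9L)
  expect_true(all(m[10:12, 10:12] == 1L))
  # corner point: block clipped to 4 pixels
  corner <- pixel_to_world(gt, 0, 0)
  m2 <- rasterize_points(new_points(corner$x, corner$y), gt, c(50, 50))
  expect_equal(sum(m2), 4L)
  # two points one pixel apart merge into one binary region
  p2 <- pixel_to_world(gt, c(10, 11), c(10, 10))
  m3 <- rasterize_points(new_points(p2$x, p2$y), gt, c(50, 50))
  expect_equal(sum(m3), 12L)
  expect_true(all(m3 %in% c(0L, 1L)))
  # out-of-patch points are ignored but counted
  m4 <- rasterize_points(new_points(c(-10, interior$x), c(0, interior$y)),
                         gt, c(50, 50))
  expect_equal(sum(m4), 9L)
  expect_equal(attr(m4, "n_outside"), 1L)
  expect_equal(sum(rasterize_points(new_points(), gt, c(50, 50))), 0L)
  expect_error(rasterize_points(new_points(1, 1), gt, c(50, 50), size = 2),
               "odd")
})

test_that("rasterize then centroid recovers the original pixel", {
  gt <- list(origin = c(-30, 200), pixel_size = 0.5)
  for (rc in list(c(5L, 9L), c(20L, 3L), c(40L, 40L))) {
    w <- pixel_to_world(gt, rc[1], rc[2])
    m <- rasterize_points(new_points(w$x, w$y), gt, c(48, 48))
    seg <- label_segments(m, 8L)[[1]]
    expect_equal(c(mean(seg$row), mean(seg$col)), as.numeric(rc))
  }
})

test_that("augmentation preserves alignment, counts and group structure", {
  tile <- make_tile(21, size = 48)
  aug <- augment_pair(tile[c("image", "mask")])
  expect_named(aug, c("identity", "hflip", "vflip", "rot90"))
  for (a in aug) {
    expect_equal(sum(a$mask), sum(tile$mask))
    expect_equal(dim(a$image), dim(tile$image))
    # image and mask transformed identically: mask pixels stay dark
    animal_px <- a$image[, , 1][a$mask == 1]
    expect_lt(mean(animal_px), mean(a$image[, , 1]))
  }
  # involution and order-4 rotation
  hh <- augment_pair(aug$hflip)$hflip
  expect_equal(hh$mask, tile$mask, ignore_attr = TRUE)
  r <- tile[c("image", "mask")]
  for (i in 1:4) r <- augment_pair(r)$rot90
  expect_equal(r$mask, tile$mask, ignore_attr = TRUE)
  expect_equal(r$image, tile$image)
})

test_that("fold splitting is balanced, seeded and validated", {
  f <- split_folds(sprintf("p%03d", 1:100), K = 10, seed = 4)
  expect_equal(as.vector(table(f$fold)), rep(10L, 10))
  expect_identical(f, split_folds(sprintf("p%03d", 1:100), K = 10, seed = 4))
  expect_false(identical(f$fold,
                         split_folds(sprintf("p%03d", 1:100), 10, 5)$fold))
  f2 <- split_folds(1:25, K = 10, seed = 1)
  expect_true(all(table(f2$fold) %in% c(2L, 3L)))
  expect_error(split_folds(1:9, K = 10, seed = 1), "cannot fill")
  expect_error(split_folds(1:9, K = 1, seed = 1), ">= 2")
})

test_that("density strata follow the mean/sd breakpoints", {
  # counts engineered to mu = 10 and sigma = 5 exactly
  counts <- setNames(c(5, 5, 10, 15, 15), paste0("c", 1:5))
  expect_equal(mean(counts), 10)
  expect_equal(sd(counts), 5)
  strata <- stratify_cells(counts)
  expect_equal(as.character(strata),
               c("low", "low", "medium", "high", "high"))
  # half-open intervals: mu+sigma belongs to high, mu+2*sigma to very_high
  counts2 <- setNames(c(21, 8, 8, 8, 8, 8, 9), paste0("d", 1:7))
  mu <- mean(counts2); sig <- sd(counts2)
  s2 <- stratify_cells(counts2)
  expect_equal(as.character(s2[counts2 >= mu + 2 * sig]), "very_high")
  expect_true(all(as.character(s2[counts2 < mu]) == "low"))
  # degenerate: all equal -> all medium
  s3 <- stratify_cells(c(a = 7, b = 7, c = 7))
  expect_true(all(s3 == "medium"))
  expect_error(stratify_cells(numeric()), ">= 1")
})

test_that("stratified sampling is proportionate within one cell", {
  set.seed(9)
  counts <- setNames(c(rpois(60, 2), rpois(30, 10), rpois(10, 30)),
                     sprintf("g%03d", 1:100))
  strata <- stratify_cells(counts)
  picked <- sample_stratified(strata, 40, seed = 2)
  expect_equal(length(picked), 40L)
  expect_true(!anyDuplicated(picked))
  tab <- table(strata)
  got <- table(strata[picked])
  expected <- as.numeric(tab) / 100 * 40
  expect_true(all(abs(as.numeric(got) - expected) <= 1))
  expect_identical(picked, sample_stratified(strata, 40, seed = 2))
})
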
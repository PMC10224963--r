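test_that("matching radius is the pixel diagonal", {
  r <- matching_radius(0.5)
  expect_equal(attr(r, "display"), 0.71)
  expect_equal(as.numeric(r), sqrt(2) * 0.5)
  expect_equal(attr(matching_radius(1), "display"), 1.41)
  expect_error(matching_radius(0), "positive")
})

test_that("point matching honors the inclusive boundary and one-to-one rule", {
  radius <- sqrt(2) / 2
  # exactly on the boundary: TP
  m <- match_points(data.frame(x = 0, y = 0), data.frame(x = 0.5, y = 0.5),
                    radius)
  expect_equal(nrow(m$tp_pairs), 1L)
  # just beyond: FP + FN
  m2 <- match_points(data.frame(x = 0, y = 0), data.frame(x = 1, y = 0),
                     0.71)
  expect_equal(nrow(m2$tp_pairs), 0L)
  expect_equal(m2$fp, 1L)
  expect_equal(m2$fn, 1L)
  # two predictions near one reference: one TP, one FP, closest wins
  m3 <- match_points(data.frame(x = c(0.1, 0.3), y = c(0, 0)),
                     data.frame(x = 0, y = 0), radius)
  expect_equal(nrow(m3$tp_pairs), 1L)
  expect_equal(m3$tp_pairs$pred, 1L)
  expect_equal(m3$fp, 2L)
  # empty sides
  m4 <- match_points(data.frame(x = numeric(), y = numeric()),
                     data.frame(x = 1, y = 1), 1)
  expect_equal(m4$fn, 1L)
})

test_that("every point lands in exactly one bucket", {
  set.seed(42)
  for (rep in 1:20) {
    pred <- data.frame(x = runif(15, 0, 10), y = runif(15, 0, 10))
    ref <- data.frame(x = runif(12, 0, 10), y = runif(12, 0, 10))
    m <- match_points(pred, ref, 1.2)
    expect_setequal(c(m$tp_pairs$pred, m$fp), seq_len(15))
    expect_setequal(c(m$tp_pairs$ref, m$fn), seq_len(12))
    expect_true(all(m$tp_pairs$dist <= 1.2))
  }
})

test_that("greedy matching never beats and usually equals the optimal assignment", {
  set.seed(7)
  radius <- 1
  n_equal <- 0
  for (rep in 1:60) {
    np <- sample(0:10, 1); nr <- sample(0:10, 1)
    pred <- data.frame(x = runif(np, 0, 6), y = runif(np, 0, 6))
    ref <- data.frame(x = runif(nr, 0, 6), y = runif(nr, 0, 6))
    tp_greedy <- nrow(match_points(pred, ref, radius)$tp_pairs)
    tp_opt <- max_matching_tp(pred, ref, radius)
    expect_lte(tp_greedy, tp_opt)
    if (tp_greedy == tp_opt) n_equal <- n_equal + 1
  }
  expect_gt(n_equal, 40)  # ties are the norm on sparse instances
})

test_that("metrics follow the precision/recall/F1 definitions", {
  m <- compute_metrics(tp = 7, fp = 3, fn = 1)
  expect_equal(m$precision, 0.7)
  expect_equal(m$recall, 7 / 8)
  expect_equal(m$f1, 2 * 0.7 * (7 / 8) / (0.7 + 7 / 8))
  # degenerate zero cases
  z <- compute_metrics(tp = 0, fp = 0, fn = 0)
  expect_equal(unlist(z[c("precision", "recall", "f1")]),
               c(precision = 0, recall = 0, f1 = 0))
  # harmonic-mean identities
  expect_equal(f1_score(0.6, 0.6), 0.6)
  set.seed(3)
  p <- runif(50); r <- runif(50)
  f <- f1_score(p, r)
  expect_true(all(f <= (p + r) / 2 + 1e-12))
  expect_true(all(pmin(p, r) >= f / 2 - 1e-12))
})

test_that("trapezoidal AUC reproduces closed-form areas", {
  expect_equal(pr_auc(c(0, 1), c(1, 0)), 0.5)
  expect_equal(pr_auc(c(0, 1, 1), c(1, 1, 0)), 1.0)
  expect_equal(pr_auc(c(0, 0.5, 1), c(1, 0.5, 0)), 0.5)
  # unsorted input is sorted by recall first
  expect_equal(pr_auc(c(1, 0), c(0, 1)), 0.5)
})

test_that("pr_curve sweeps the full post-processing chain", {
  set.seed(19)
  gt <- list(origin = c(0, 50), pixel_size = 0.5)
  w <- pixel_to_world(gt, c(10, 30, 70), c(10, 40, 80))
  truth <- new_points(w$x, w$y)
  p <- generate_oracle_probmap(truth, gt, c(100, 100), noise_level = 0.3)
  curve <- pr_curve(list(p), list(truth), gt,
                    thresholds = seq(0.1, 0.9, 0.2),
                    radius = matching_radius(0.5))
  expect_s3_class(curve, "wd_prcurve")
  expect_equal(curve$points$recall[1], 0)
  expect_equal(curve$points$precision[1], 1)
  expect_equal(curve$points$recall[nrow(curve$points)], 1)
  expect_true(curve$auc >= 0 && curve$auc <= 1)
  # noise below every threshold: mid thresholds are perfect
  mid <- curve$points[!is.na(curve$points$threshold) &
                        curve$points$threshold == 0.5, ]
  expect_equal(mid$precision, 1)
  expect_equal(mid$recall, 1)
  expect_error(pr_curve(list(p), list(truth), gt, thresholds = numeric(),
                        radius = 1), "threshold")
})

test_that("match results export as status-tagged GeoJSON", {
  pred <- data.frame(x = c(0, 5), y = c(0, 0))
  ref <- data.frame(x = c(0.1, 9), y = c(0, 9))
  m <- match_points(pred, ref, 1)
  path <- file.path(tempdir(), "match.geojson")
  write_match_geojson(m, pred, ref, path)
  gj <- jsonlite::read_json(path)
  status <- vapply(gj$features, function(f) f$properties$status, "")
  expect_equal(sort(status), c("FN", "FP", "TP"))
})

test_that("leave-one-group-out splits are disjoint and complete", {
  groups <- setNames(rep(c("2009", "2010", "2015"), each = 4),
                     sprintf("p%02d", 1:12))
  sp <- transfer_protocol(groups, "2015")
  expect_length(sp$train_ids, 8L)
  expect_length(sp$test_ids, 4L)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0L)
  expect_setequal(c(sp$train_ids, sp$test_ids), names(groups))
  # held-out patches never enter a fold
  folds <- split_folds(sp$train_ids, K = 4, seed = 1)
  expect_length(intersect(folds$id, sp$test_ids), 0L)
  expect_error(transfer_protocol(groups, "1999"), "not present")
})
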
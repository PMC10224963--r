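#' Detection configuration
#'
#' @param prob_threshold probability cut for the fused map; ties at the
#'   threshold are positive (`>=`). Default 0.5.
#' @param connectivity pixel connectivity for segment labeling, 4 or 8;
#'   8 by default so diagonal 3-4 px animal bodies do not fragment.
#' @param object_size_px pixel footprint of one animal; a merged segment of
#'   `n` pixels is split into `ceiling(n / object_size_px)` individuals.
#'   Default 9 (a 3x3 block).
#' @param kmeans_seed integer seed for the K-means splits.
#' @return list of class `wd_detect_config`.
#' @export
detect_config <- function(prob_threshold = 0.5, connectivity = 8L,
                          object_size_px = 9L, kmeans_seed = 1L) {
  if (prob_threshold <= 0 || prob_threshold >= 1)
    stopf("prob_threshold must be in (0, 1)")
  if (!connectivity %in% c(4L, 8L)) stopf("connectivity must be 4 or 8")
  if (object_size_px < 1) stopf("object_size_px must be >= 1")
  structure(list(prob_threshold = prob_threshold,
                 connectivity = as.integer(connectivity),
                 object_size_px = as.integer(object_size_px),
                 kmeans_seed = as.integer(kmeans_seed)),
            class = "wd_detect_config")
}

#' Threshold a probability map into a binary mask
#'
#' @param p probability matrix in `[0, 1]`.
#' @param threshold cut value; pixels with `p >= threshold` are positive.
#' @return integer 0/1 matrix.
#' @export
binarize <- function(p, threshold = 0.5) {
  m <- matrix(0L, nrow(p), ncol(p))
  m[p >= threshold] <- 1L
  m
}

#' Label connected components of a binary mask
#'
#' Maximal connected sets of positive pixels under 4- or 8-connectivity.
#'
#' @param mask binary matrix.
#' @param connectivity 4 or 8.
#' @return list of segments, each a data.frame with 0-based `row`, `col`.
#' @export
label_segments <- function(mask, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) stopf("connectivity must be 4 or 8")
  lab <- cc_label_cpp(mask != 0, as.integer(connectivity))
  n <- max(lab)
  if (n == 0) return(list())
  idx <- which(lab > 0, arr.ind = TRUE)
  split(data.frame(row = idx[, 1] - 1L, col = idx[, 2] - 1L),
        lab[lab > 0]) |> unname()
}

#' Number of individuals in a merged segment
#'
#' Ceiling division of the segment's pixel count by the per-animal
#' footprint: a 9-pixel segment is one animal, a 10-pixel segment two.
#'
#' @param n_pixels segment size in pixels (>= 1).
#' @param object_size_px per-animal footprint, default 9.
#' @return integer cluster count.
#' @export
clusters_for_segment <- function(n_pixels, object_size_px = 9L) {
  if (any(n_pixels < 1)) stopf("segments must be non-empty")
  as.integer(ceiling(n_pixels / object_size_px))
}

#' Split a segment into k individuals by K-means
#'
#' Runs seeded K-means (k-means++-like behavior via multiple random
#' restarts, best inertia kept) on the segment's pixel coordinates and
#' returns the k cluster centroids; for `k = 1` this is the segment
#' centroid. Centroids lie within the segment's bounding box.
#'
#' @param seg data.frame with 0-based `row`, `col` pixel coordinates.
#' @param k number of clusters, `1 <= k <= nrow(seg)`.
#' @param seed integer seed making the split deterministic.
#' @return data.frame with fractional pixel coordinates `row`, `col`.
#' @export
split_segment <- function(seg, k, seed = 1L) {
  n <- nrow(seg)
  if (k > n) stopf("cannot split %d pixels into %d clusters", n, k)
  if (k == 1)
    return(data.frame(row = mean(seg$row), col = mean(seg$col)))
  if (k == n)
    return(data.frame(row = as.numeric(seg$row), col = as.numeric(seg$col)))
  cm <- with_seed(seed, suppressWarnings(
    stats::kmeans(cbind(seg$row, seg$col), centers = k, nstart = 10L,
                  iter.max = 50L)))
  data.frame(row = cm$centers[, 1], col = cm$centers[, 2])
}

#' Convert a probability map into animal points
#'
#' The post-processing block: threshold at `prob_threshold`, label
#' connected components, split each segment into
#' `ceiling(pixels / object_size_px)` individuals by K-means, and return
#' the centroids as world-coordinate points. Each point carries the mean
#' fused probability of its segment as `score`.
#'
#' @param p probability matrix.
#' @param gt geotransform of the map.
#' @param dconfig a [detect_config()].
#' @return a `wd_points` with `source_tag = "prediction"`.
#' @export
detect_from_probmap <- function(p, gt, dconfig = detect_config()) {
  mask <- binarize(p, dconfig$prob_threshold)
  segs <- label_segments(mask, dconfig$connectivity)
  if (!length(segs)) return(new_points(source_tag = "prediction"))
  out <- vector("list", length(segs))
  for (i in seq_along(segs)) {
    seg <- segs[[i]]
    k <- clusters_for_segment(nrow(seg), dconfig$object_size_px)
    ctr <- split_segment(seg, k, seed = derive_seed(dconfig$kmeans_seed, i))
    sc <- mean(p[cbind(seg$row + 1, seg$col + 1)])
    out[[i]] <- cbind(ctr, score = sc)
  }
  ctrs <- do.call(rbind, out)
  w <- pixel_to_world(gt, ctrs$row, ctrs$col)
  new_points(w$x, w$y, score = pmin(pmax(ctrs$score, 0), 1),
             source_tag = "prediction")
}

#' Detect animals across a whole scene
#'
#' Tiles the scene on the standard grid (overlap-free, matching the
#' training patch layout), computes the fused ensemble probability map per
#' tile, post-processes each tile into points and concatenates the results
#' in world coordinates. Partial border tiles are zero-padded for inference
#' and predictions cropped back to the valid window. Note that with
#' overlap-free tiling an animal straddling a tile seam can be reported by
#' both tiles.
#'
#' @param models the probability source: a list of trained U-Net models
#'   (ensemble), a single model, a `function(patch_array) -> matrix`, or a
#'   precomputed scene-wide probability matrix (e.g. an oracle map).
#' @param scene a `wd_scene`.
#' @param dconfig a [detect_config()].
#' @param econfig an [ensemble_config()] (rescale gate for base-model maps).
#' @param patch_px inference tile edge in pixels.
#' @return a `wd_points` of detections with per-point mean fused
#'   probability as `score`.
#' @export
detect_scene <- function(models, scene, dconfig = detect_config(),
                         econfig = ensemble_config(), patch_px = 336L) {
  stopifnot(is_scene(scene))
  if (is.matrix(models)) {
    if (!all(dim(models) == scene_dim(scene)))
      stopf("probability map does not match scene dimensions")
    return(detect_from_probmap(models, geotransform(scene), dconfig))
  }
  grid <- build_grid(scene, patch_px)
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cell <- grid[i, ]
    patch <- extract_patch(scene, cell, pad = TRUE, patch_px = patch_px)
    arr <- normalize_patch(patch)
    pm <- predict_fused(models, arr, econfig)
    vh <- attr(patch, "valid_height"); vw <- attr(patch, "valid_width")
    pm <- pm[seq_len(vh), seq_len(vw), drop = FALSE]
    res[[i]] <- detect_from_probmap(pm, geotransform(patch), dconfig)
  }
  pts <- do.call(rbind, lapply(res, as.data.frame))
  new_points(pts$x, pts$y, score = pts$score, source_tag = "prediction")
}

# fused probability for one normalized patch array, from whatever source
predict_fused <- function(models, arr, econfig = ensemble_config()) {
  if (is.function(models)) return(models(arr))
  if (inherits(models, "wd_unet")) models <- list(models)
  maps <- lapply(models, function(m)
    normalize_probmap(predict_patch(m, arr), econfig$rescale_threshold))
  fuse_probmaps(maps)
}

#' Census count with a t-based confidence interval
#'
#' Mean of repeated per-run totals with the 95% half-width
#' `t(0.975, n-1) * sd / sqrt(n)` (the t quantile matters at the n = 5
#' runs typically used); a normal-approximation flag is available for
#' comparison.
#'
#' @param counts numeric vector of per-run totals (>= 2).
#' @param level confidence level, default 0.95.
#' @param normal use the normal instead of the t quantile.
#' @return list with `mean_count`, `half_width`, `ci_low`, `ci_high`,
#'   `n_runs`.
#' @export
count_with_ci <- function(counts, level = 0.95, normal = FALSE) {
  n <- length(counts)
  if (n < 2) stopf("need >= 2 repeated counts for an interval")
  q <- if (normal) stats::qnorm(1 - (1 - level) / 2)
       else stats::qt(1 - (1 - level) / 2, df = n - 1)
  hw <- q * stats::sd(counts) / sqrt(n)
  list(mean_count = mean(counts), half_width = hw,
       ci_low = mean(counts) - hw, ci_high = mean(counts) + hw, n_runs = n)
}
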
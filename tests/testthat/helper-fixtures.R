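# fixtures and independent oracles shared across test files

# small synthetic tile with image, mask, truth and geotransform
make_tile <- function(seed, size = 96L, n_mean = 6,
                      confusers = c(bush = 2, mound_shadow = 1, road = 0,
                                    river = 0)) {
  set.seed(seed)
  spec <- scene_spec(width_px = size, height_px = size,
                     n_animals = stats::rpois(1, n_mean) + 1,
                     confusers = confusers, seed = seed)
  sim <- generate_scene(spec)
  list(image = normalize_patch(sim$scene),
       mask = rasterize_points(sim$truth, geotransform(sim$scene),
                               c(size, size)),
       truth = sim$truth, gt = geotransform(sim$scene), scene = sim$scene)
}

# toy 3-band scene with deterministic ramp values
make_toy_scene <- function(h = 96L, w = 96L, bands = 3L, pixel_size = 0.5,
                           origin = c(100, 500)) {
  arr <- array(seq_len(h * w * bands) %% 1789, c(h, w, bands))
  new_scene(arr, pixel_size = pixel_size, origin = origin,
            crs_label = "toy")
}

# independent oracle: maximum-cardinality bipartite matching TP count via
# augmenting paths on the <= radius adjacency graph
max_matching_tp <- function(pred, ref, radius) {
  np <- nrow(pred); nr <- nrow(ref)
  if (np == 0 || nr == 0) return(0L)
  d <- sqrt(outer(pred$x, ref$x, "-")^2 + outer(pred$y, ref$y, "-")^2)
  adj <- d <= radius
  match_of_ref <- rep(0L, nr)
  Recall2 <- function(p, seen) {
    for (r in which(adj[p, ])) {
      if (seen[r]) next
      seen[r] <- TRUE
      if (match_of_ref[r] == 0L || Recall2(match_of_ref[r], seen)) {
        match_of_ref[r] <<- p
        return(TRUE)
      }
    }
    FALSE
  }
  n_matched <- 0L
  for (p in seq_len(np))
    if (Recall2(p, rep(FALSE, nr))) n_matched <- n_matched + 1L
  n_matched
}

# independent oracle: exhaustive k-means over all assignments (tiny inputs)
exhaustive_kmeans_ss <- function(coords, k) {
  n <- nrow(coords)
  stopifnot(k <= n, k^n <= 4e6)
  best <- Inf
  assign <- rep(1L, n)
  repeat {
    if (length(unique(assign)) == k) {
      ss <- 0
      for (g in unique(assign)) {
        m <- coords[assign == g, , drop = FALSE]
        ctr <- colMeans(m)
        ss <- ss + sum((t(m) - ctr)^2)
      }
      if (ss < best) best <- ss
    }
    i <- 1L
    while (i <= n && assign[i] == k) { assign[i] <- 1L; i <- i + 1L }
    if (i > n) break
    assign[i] <- assign[i] + 1L
  }
  best
}

# within-cluster SS of a kmeans-style split of segment pixels
split_ss <- function(seg, centers) {
  coords <- cbind(seg$row, seg$col)
  d2 <- outer(coords[, 1], centers$row, "-")^2 +
    outer(coords[, 2], centers$col, "-")^2
  sum(apply(d2, 1, min))
}
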
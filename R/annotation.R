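#' Fuse multi-observer point labels by majority voting
#'
#' Pools the points of all observers and greedily agglomerates them into
#' local clusters: the densest neighborhood (most distinct observers within
#' `radius` of a seed point) is extracted first, each observer contributing
#' at most one (its closest) point per cluster. Clusters marked by at least
#' `min_votes` observers yield one consensus point at the coordinate mean
#' of their members. Seeding is by vote count, then total member distance,
#' then coordinates, so the result does not depend on observer order.
#'
#' @param observer_sets list of >= 2 `wd_points`, one per observer.
#' @param radius agreement radius in meters (use the evaluation module's
#'   matching radius by default).
#' @param min_votes minimum number of observers that must mark a location;
#'   default is a strict majority, `floor(n)/2 + 1`... computed as
#'   `floor(n_observers / 2) + 1`.
#' @return a `wd_points` with `source_tag = "consensus"`.
#' @export
fuse_annotations <- function(observer_sets, radius,
                             min_votes = floor(length(observer_sets) / 2) + 1) {
  n_obs <- length(observer_sets)
  if (n_obs < 2) stopf("need >= 2 observer sets")
  if (min_votes > n_obs)
    stopf("min_votes (%d) exceeds number of observers (%d)", min_votes, n_obs)
  if (!is.numeric(radius) || radius <= 0) stopf("radius must be > 0")

  pts <- do.call(rbind, lapply(seq_along(observer_sets), function(i) {
    s <- observer_sets[[i]]
    if (nrow(s) == 0) return(NULL)
    data.frame(x = s$x, y = s$y, obs = i)
  }))
  if (is.null(pts) || nrow(pts) == 0)
    return(new_points(source_tag = "consensus"))

  used <- rep(FALSE, nrow(pts))
  out_x <- numeric(); out_y <- numeric(); out_votes <- integer()
  repeat {
    avail <- which(!used)
    if (!length(avail)) break
    # for every available seed, gather closest-per-observer members in radius
    best <- NULL
    for (s in avail) {
      d <- sqrt((pts$x[avail] - pts$x[s])^2 + (pts$y[avail] - pts$y[s])^2)
      near <- avail[d <= radius]
      dn <- d[d <= radius]
      # one point per observer: keep the closest
      o <- order(pts$obs[near], dn)
      near <- near[o]; dn <- dn[o]
      keep <- !duplicated(pts$obs[near])
      members <- near[keep]; dm <- dn[keep]
      cand <- list(seed = s, members = members, votes = length(members),
                   dist = sum(dm))
      if (is.null(best) || cand$votes > best$votes ||
          (cand$votes == best$votes && cand$dist < best$dist) ||
          (cand$votes == best$votes && cand$dist == best$dist &&
           (pts$x[s] < pts$x[best$seed] ||
            (pts$x[s] == pts$x[best$seed] && pts$y[s] < pts$y[best$seed]))))
        best <- cand
    }
    if (best$votes < min_votes) break
    used[best$members] <- TRUE
    out_x <- c(out_x, mean(pts$x[best$members]))
    out_y <- c(out_y, mean(pts$y[best$members]))
    out_votes <- c(out_votes, best$votes)
  }
  res <- new_points(out_x, out_y, source_tag = "consensus")
  attr(res, "votes") <- out_votes
  attr(res, "n_dropped") <- sum(!used)
  res
}

#' Rasterize point labels into a binary mask
#'
#' Each in-patch point sets the `size` x `size` pixel block centered on its
#' pixel to 1 (the conventional 3x3 animal footprint), clipped at the patch
#' borders; overlapping blocks merge into a single binary region.
#' Out-of-patch points are ignored and counted in attribute `n_outside`.
#'
#' @param points a `wd_points` in world coordinates.
#' @param gt geotransform of the patch (scene, patch, or list with
#'   `origin`/`pixel_size`).
#' @param dim integer `(height, width)` of the mask in pixels.
#' @param size odd block edge in pixels (default 3).
#' @return binary integer matrix `height x width`.
#' @export
rasterize_points <- function(points, gt, dim, size = 3L) {
  if (size %% 2 != 1) stopf("block size must be odd")
  h <- dim[1]; w <- dim[2]
  m <- matrix(0L, h, w)
  if (nrow(points) == 0) return(m)
  pc <- world_to_pixel(gt, points$x, points$y)
  r <- round(pc$row); c <- round(pc$col)
  inside <- r >= 0 & r < h & c >= 0 & c < w
  half <- (size - 1L) / 2L
  for (i in which(inside)) {
    rr <- max(0, r[i] - half):min(h - 1, r[i] + half)
    cc <- max(0, c[i] - half):min(w - 1, c[i] + half)
    m[rr + 1, cc + 1] <- 1L
  }
  attr(m, "n_outside") <- sum(!inside)
  m
}

#' Augment a patch/mask pair
#'
#' Returns the four variants used for training-set expansion: identity,
#' horizontal flip, vertical flip, and 90-degree rotation, with image and
#' mask transformed identically.
#'
#' @param pair list with `image` (array H x W x B) and `mask` (matrix H x W).
#' @return named list of four pairs: `identity`, `hflip`, `vflip`, `rot90`.
#' @export
augment_pair <- function(pair) {
  img <- pair$image; msk <- pair$mask
  if (!all(dim(img)[1:2] == dim(msk)))
    stopf("image and mask dimensions differ")
  ap <- function(f) list(image = apply_bands(img, f), mask = f(msk))
  list(identity = list(image = img, mask = msk),
       hflip = ap(flip_h), vflip = ap(flip_v), rot90 = ap(rot90ccw))
}

flip_h <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
flip_v <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]
rot90ccw <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]

apply_bands <- function(arr, f) {
  out <- NULL
  for (b in seq_len(dim(arr)[3])) {
    tb <- f(arr[, , b])
    if (is.null(out)) out <- array(0, c(dim(tb), dim(arr)[3]))
    out[, , b] <- tb
  }
  out
}

#' Split patches into K balanced folds
#'
#' Seeded, reproducible partition into `K` folds whose sizes differ by at
#' most one; the basis of the K-fold ensemble (one base model is validated
#' on each fold and trained on the rest).
#'
#' @param patch_ids vector of patch identifiers.
#' @param K number of folds (default 10).
#' @param seed integer seed.
#' @return data.frame with columns `id`, `fold` (0-based); `K` is kept as
#'   an attribute.
#' @export
split_folds <- function(patch_ids, K = 10L, seed = 1L) {
  n <- length(patch_ids)
  if (K < 2) stopf("K must be >= 2")
  if (n < K) stopf("%d patches cannot fill %d folds", n, K)
  perm <- with_seed(seed, sample.int(n))
  fold <- integer(n)
  fold[perm] <- rep_len(seq_len(K) - 1L, n)
  out <- data.frame(id = patch_ids, fold = fold)
  attr(out, "K") <- as.integer(K)
  out
}

#' Stratify grid cells by animal density
#'
#' With `mu` and `sigma` the mean and standard deviation of per-cell animal
#' counts, cells are assigned to four density strata:
#' low `[0, mu)`, medium `[mu, mu + sigma)`, high `[mu + sigma, mu + 2 sigma)`,
#' very_high `[mu + 2 sigma, Inf)`. When `sigma = 0` (all cells equal) every
#' cell is assigned `medium`. The density map may come from manual counts or
#' from a preliminary model's detections.
#'
#' @param density_per_cell named numeric vector of per-cell counts.
#' @return factor with levels `low`, `medium`, `high`, `very_high`.
#' @export
stratify_cells <- function(density_per_cell) {
  if (!length(density_per_cell)) stopf("need >= 1 cell")
  mu <- mean(density_per_cell); sig <- stats::sd(density_per_cell)
  if (length(density_per_cell) == 1L || is.na(sig)) sig <- 0
  lv <- c("low", "medium", "high", "very_high")
  if (sig == 0) {
    f <- factor(rep("medium", length(density_per_cell)), levels = lv)
  } else {
    idx <- findInterval(density_per_cell, c(mu, mu + sig, mu + 2 * sig)) + 1L
    f <- factor(lv[idx], levels = lv)
  }
  names(f) <- names(density_per_cell)
  f
}

#' Proportionate stratified random sample of cells
#'
#' Draws `n_total` cells with per-stratum sample sizes proportional to
#' stratum sizes (largest-remainder apportionment, so each stratum's quota
#' deviates from exact proportionality by at most one cell), then samples
#' uniformly without replacement inside each stratum.
#'
#' @param strata factor as returned by [stratify_cells()] (named by cell).
#' @param n_total number of cells to draw.
#' @param seed integer seed.
#' @return character vector of sampled cell names.
#' @export
sample_stratified <- function(strata, n_total, seed = 1L) {
  if (n_total > length(strata)) stopf("cannot sample %d of %d cells",
                                      n_total, length(strata))
  tab <- table(strata)
  quota_f <- as.numeric(tab) / length(strata) * n_total
  quota <- floor(quota_f)
  rem <- n_total - sum(quota)
  if (rem > 0) {
    o <- order(quota_f - quota, decreasing = TRUE)
    quota[o[seq_len(rem)]] <- quota[o[seq_len(rem)]] + 1L
  }
  quota <- pmin(quota, as.numeric(tab))  # tiny strata cannot overdraw
  with_seed(seed, {
    unlist(lapply(seq_along(tab), function(i) {
      members <- names(strata)[strata == names(tab)[i]]
      sample(members, quota[i])
    }), use.names = FALSE)
  })
}
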
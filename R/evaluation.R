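#' Matching radius from pixel size
#'
#' Point detections are matched to references within the ground length of
#' one pixel diagonal, `sqrt(2) * pixel_size` — 0.71 m at 0.5 m resolution
#' (the full-precision value is used internally; the 2-decimal form is for
#' display). This absorbs the one-pixel centroid shifts expected when an
#' animal's segment is not a perfect 3x3 square.
#'
#' @param pixel_size meters per pixel.
#' @return matching radius in meters (full precision), with the rounded
#'   display value as attribute `display`.
#' @export
matching_radius <- function(pixel_size) {
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stopf("pixel_size must be a single positive number")
  r <- sqrt(2) * pixel_size
  attr(r, "display") <- round(r, 2)
  r
}

#' One-to-one point matching within a radius
#'
#' Pairs predicted and reference points greedily on globally
#' distance-sorted candidate pairs (ties broken by prediction then
#' reference index): the closest still-unmatched pair within `radius` is
#' accepted until none remains. Matched predictions are true positives,
#' unmatched predictions false positives, unmatched references false
#' negatives. The boundary is inclusive (`distance <= radius`).
#'
#' @param pred,ref `wd_points` (or data.frames with `x`, `y`).
#' @param radius matching radius in meters.
#' @return object of class `wd_match`: list with `tp_pairs` (data.frame
#'   `pred`, `ref`, `dist` of matched index pairs), `fp` (unmatched
#'   prediction indices), `fn` (unmatched reference indices).
#' @export
match_points <- function(pred, ref, radius) {
  if (!is.numeric(radius) || radius <= 0) stopf("radius must be > 0")
  np <- nrow(pred); nr <- nrow(ref)
  if (np == 0 || nr == 0) {
    res <- list(tp_pairs = data.frame(pred = integer(), ref = integer(),
                                      dist = numeric()),
                fp = seq_len(np), fn = seq_len(nr))
    class(res) <- "wd_match"
    return(res)
  }
  dx <- outer(pred$x, ref$x, "-"); dy <- outer(pred$y, ref$y, "-")
  d <- sqrt(dx^2 + dy^2)
  cand <- which(d <= radius, arr.ind = TRUE)
  tp <- data.frame(pred = integer(), ref = integer(), dist = numeric())
  if (nrow(cand)) {
    dd <- d[cand]
    o <- order(dd, cand[, 1], cand[, 2])
    cand <- cand[o, , drop = FALSE]; dd <- dd[o]
    p_used <- rep(FALSE, np); r_used <- rep(FALSE, nr)
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      pi <- cand[i, 1]; ri <- cand[i, 2]
      if (!p_used[pi] && !r_used[ri]) {
        p_used[pi] <- TRUE; r_used[ri] <- TRUE; keep[i] <- TRUE
      }
    }
    tp <- data.frame(pred = cand[keep, 1], ref = cand[keep, 2],
                     dist = dd[keep])
  }
  res <- list(tp_pairs = tp,
              fp = setdiff(seq_len(np), tp$pred),
              fn = setdiff(seq_len(nr), tp$ref))
  class(res) <- "wd_match"
  res
}

#' @export
print.wd_match <- function(x, ...) {
  cat(sprintf("<wd_match> TP %d, FP %d, FN %d\n", nrow(x$tp_pairs),
              length(x$fp), length(x$fn)))
  invisible(x)
}

#' Precision, recall and F1 from a match result
#'
#' Precision is TP / (TP + FP), recall TP / (TP + FN), and the F1-score
#' their harmonic mean; 0/0 ratios are defined as 0.
#'
#' @param m a `wd_match`, or omit and give counts directly.
#' @param tp,fp,fn counts (used when `m` is missing).
#' @return list with `precision`, `recall`, `f1`, `tp`, `fp`, `fn`.
#' @export
compute_metrics <- function(m = NULL, tp = NULL, fp = NULL, fn = NULL) {
  if (!is.null(m)) {
    tp <- nrow(m$tp_pairs); fp <- length(m$fp); fn <- length(m$fn)
  }
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  list(precision = p, recall = r, f1 = f1_score(p, r),
       tp = tp, fp = fp, fn = fn)
}

#' Harmonic mean of precision and recall
#'
#' @param precision,recall fractions (or percentages; the result is on the
#'   same scale).
#' @return the F1-score; 0 when both inputs are 0.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Trapezoidal area under a precision-recall curve
#'
#' Composite trapezoidal rule over recall-sorted points. The conventional
#' endpoints `(recall 0, precision 1)` and `(recall 1, precision 0)` are
#' the caller's responsibility (added by [pr_curve()]); with endpoints
#' alone the AUC is 0.5.
#'
#' @param recall,precision numeric vectors of equal length.
#' @return area in `[0, 1]`.
#' @export
pr_auc <- function(recall, precision) {
  o <- order(recall, -precision)
  r <- recall[o]; p <- precision[o]
  sum(diff(r) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
}

#' Precision-recall curve of a detector over a threshold sweep
#'
#' For every threshold the full post-processing chain is run on each
#' probability map (binarize, connected components, ceiling-rule K-means
#' split), the resulting points are matched against the references within
#' `radius`, and TP/FP/FN are pooled across maps. The endpoint pairs
#' `(0, 1)` and `(1, 0)` for thresholds 1 and 0 are appended and the AUC is
#' computed by the composite trapezoidal rule.
#'
#' @param probmaps list of probability matrices (one per tile).
#' @param refs list of `wd_points` (world coordinates), parallel to
#'   `probmaps`.
#' @param gts list of geotransforms, parallel to `probmaps` (or one shared).
#' @param thresholds strictly increasing values in (0, 1); default
#'   `seq(0.05, 0.95, by = 0.05)`.
#' @param radius matching radius in meters.
#' @param dconfig detection configuration, see [detect_config()]; its
#'   `prob_threshold` is overridden by the sweep.
#' @return list of class `wd_prcurve`: `points` (data.frame `threshold`,
#'   `recall`, `precision`; endpoint rows have threshold NA) and `auc`.
#' @export
pr_curve <- function(probmaps, refs, gts, thresholds = seq(0.05, 0.95, 0.05),
                     radius, dconfig = detect_config()) {
  if (!length(thresholds)) stopf("need >= 1 threshold")
  if (any(diff(thresholds) <= 0)) stopf("thresholds must be increasing")
  if (!is.list(gts) || !is.null(gts$origin)) gts <- rep(list(gts), length(probmaps))
  rows <- lapply(thresholds, function(th) {
    dconfig$prob_threshold <- th
    tp <- fp <- fn <- 0L
    for (i in seq_along(probmaps)) {
      det <- detect_from_probmap(probmaps[[i]], gts[[i]], dconfig)
      m <- match_points(det, refs[[i]], radius)
      tp <- tp + nrow(m$tp_pairs); fp <- fp + length(m$fp)
      fn <- fn + length(m$fn)
    }
    mt <- compute_metrics(tp = tp, fp = fp, fn = fn)
    data.frame(threshold = th, recall = mt$recall, precision = mt$precision)
  })
  pts <- do.call(rbind, rows)
  pts <- rbind(data.frame(threshold = NA, recall = 0, precision = 1),
               pts,
               data.frame(threshold = NA, recall = 1, precision = 0))
  res <- list(points = pts, auc = pr_auc(pts$recall, pts$precision))
  class(res) <- "wd_prcurve"
  res
}

#' @export
print.wd_prcurve <- function(x, ...) {
  cat(sprintf("<wd_prcurve> %d points, AUC %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Export a match result as GeoJSON for map rendering
#'
#' One Point feature per prediction and per unmatched reference, each with
#' a `status` property of `"TP"`, `"FP"` or `"FN"` — the conventional
#' crosses-on-imagery evaluation display.
#'
#' @param m a `wd_match` from [match_points()].
#' @param pred,ref the point sets that were matched.
#' @param path output `.geojson` path.
#' @export
write_match_geojson <- function(m, pred, ref, path) {
  feat <- function(x, y, status)
    list(type = "Feature",
         geometry = list(type = "Point", coordinates = c(x, y)),
         properties = list(status = status))
  feats <- c(
    lapply(m$tp_pairs$pred, function(i) feat(pred$x[i], pred$y[i], "TP")),
    lapply(m$fp, function(i) feat(pred$x[i], pred$y[i], "FP")),
    lapply(m$fn, function(i) feat(ref$x[i], ref$y[i], "FN")))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Leave-one-group-out transfer split
#'
#' Holds out every patch of one acquisition group (e.g. a year) from
#' training and fold assignment; evaluation is then restricted to the
#' held-out group. Used to probe temporal/spatial transferability.
#'
#' @param groups named vector mapping patch id -> group label.
#' @param hold_out_group label to hold out.
#' @return list with `train_ids` and `test_ids`.
#' @export
transfer_protocol <- function(groups, hold_out_group) {
  if (!hold_out_group %in% groups)
    stopf("group '%s' not present", hold_out_group)
  list(train_ids = names(groups)[groups != hold_out_group],
       test_ids = names(groups)[groups == hold_out_group])
}
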
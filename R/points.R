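#' Construct a point set
#'
#' Georeferenced animal points: manual labels, observer consensus, or model
#' detections, with an optional per-point score in `[0, 1]`.
#'
#' @param x,y world coordinates in meters.
#' @param score optional per-point value in `[0, 1]`.
#' @param source_tag provenance label ("observer-1", "consensus",
#'   "prediction", ...).
#' @return data.frame of class `wd_points` with columns `x`, `y` and
#'   optionally `score`; the source tag is kept as an attribute.
#' @export
new_points <- function(x = numeric(), y = numeric(), score = NULL,
                       source_tag = "unknown") {
  if (length(x) != length(y)) stopf("x and y lengths differ")
  df <- data.frame(x = as.numeric(x), y = as.numeric(y))
  if (!is.null(score)) {
    if (length(score) != length(x)) stopf("score length mismatch")
    if (length(score) && (min(score) < 0 || max(score) > 1))
      stopf("scores must lie in [0, 1]")
    df$score <- as.numeric(score)
  }
  attr(df, "source_tag") <- source_tag
  class(df) <- c("wd_points", "data.frame")
  df
}

#' @rdname new_points
#' @param p object to test
#' @export
is_points <- function(p) inherits(p, "wd_points")

#' Read and write point sets
#'
#' CSV carries columns `x`, `y` and optionally `score`, `source`; GeoJSON
#' is a FeatureCollection of Point geometries with the same properties.
#' The format is chosen from the file extension.
#'
#' @param points a `wd_points` (or plain data.frame with x/y).
#' @param path file ending in `.csv` or `.geojson`/`.json`.
#' @return `read_points()` returns a `wd_points`; `write_points()` returns
#'   `path` invisibly.
#' @export
write_points <- function(points, path) {
  tag <- attr(points, "source_tag") %||% "unknown"
  if (grepl("\\.csv$", path)) {
    df <- as.data.frame(points)
    df$source <- tag
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    feats <- lapply(seq_len(nrow(points)), function(i) {
      props <- list(source = tag)
      if (!is.null(points$score)) props$score <- points$score[i]
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = c(points$x[i], points$y[i])),
           properties = props)
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_points
#' @export
read_points <- function(path) {
  if (!file.exists(path)) stopf("point file not found: %s", path)
  if (grepl("\\.csv$", path)) {
    df <- utils::read.csv(path)
    new_points(df$x, df$y, score = df$score,
               source_tag = if (!is.null(df$source) && nrow(df))
                 df$source[1] else "unknown")
  } else {
    gj <- jsonlite::read_json(path, simplifyVector = FALSE)
    coords <- vapply(gj$features, function(f)
      unlist(f$geometry$coordinates)[1:2], numeric(2))
    scores <- vapply(gj$features, function(f)
      as.numeric(f$properties$score %||% NA_real_), numeric(1))
    tag <- if (length(gj$features))
      gj$features[[1]]$properties$source %||% "unknown" else "unknown"
    if (length(gj$features) == 0)
      return(new_points(source_tag = tag))
    new_points(coords[1, ], coords[2, ],
               score = if (!anyNA(scores)) scores else NULL, source_tag = tag)
  }
}

#' Check that points fall inside a scene
#'
#' @param points a `wd_points`.
#' @param scene a `wd_scene`.
#' @return logical vector, TRUE for points inside the scene bounds.
#' @export
points_in_scene <- function(points, scene) {
  d <- scene_dim(scene)
  px <- scene$pixel_size
  points$x >= scene$origin[1] & points$x <= scene$origin[1] + d[2] * px &
    points$y <= scene$origin[2] & points$y >= scene$origin[2] - d[1] * px
}
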
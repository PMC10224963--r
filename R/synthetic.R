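#' Specification of a synthetic satellite scene
#'
#' The generator emulates the imaging conditions of sub-meter multispectral
#' wildlife surveys: 4-band (R, G, B, NIR) 11-bit radiometry, a
#' low-frequency savanna background texture, animals rendered as 3-4 pixel
#' long, 1-3 pixel wide dark blobs with 1-2 darker central pixels, herd
#' aggregation that is scattered, linear (trail-following) or clustered
#' (parent-offspring Thomas process), and confuser objects — small bushes,
#' termite-mound shadows, roads and riverbank shadows — that are larger or
#' differently shaped than animals.
#'
#' @param width_px,height_px scene size in pixels.
#' @param pixel_size ground sample distance in meters (default 0.5).
#' @param n_animals number of animals to place.
#' @param aggregation one of `"scattered"`, `"linear"`, `"clustered"`.
#' @param cluster_parents number of herd nuclei for `"clustered"`.
#' @param cluster_spread within-herd standard deviation in meters.
#' @param animal_length_px,animal_width_px,dark_center_px integer ranges
#'   (length 2) of the animal footprint, in pixels.
#' @param contrast relative intensity drop of an animal against the local
#'   background (0.45 renders clearly visible, high-contrast animals).
#' @param confusers named counts of `bush`, `mound_shadow`, `road`, `river`.
#' @param background_texture_scale correlation length of the background
#'   texture in meters.
#' @param min_sep_px minimum Chebyshev separation between animal centers in
#'   pixels (scattered placement; clustered/linear allow near-contact).
#' @param seed integer seed; scenes are bit-reproducible given the spec.
#' @return list of class `wd_scene_spec`.
#' @export
scene_spec <- function(width_px = 336L, height_px = 336L, pixel_size = 0.5,
                       n_animals = 50L, aggregation = "scattered",
                       cluster_parents = 5L, cluster_spread = 5,
                       animal_length_px = c(3L, 4L),
                       animal_width_px = c(1L, 3L),
                       dark_center_px = c(1L, 2L), contrast = 0.45,
                       confusers = c(bush = 5, mound_shadow = 3, road = 1,
                                     river = 0),
                       background_texture_scale = 20, min_sep_px = 5,
                       seed = 1L) {
  aggregation <- match.arg(aggregation, c("scattered", "linear", "clustered"))
  if (n_animals < 0) stopf("n_animals must be >= 0")
  if (contrast <= 0 || contrast > 0.9) stopf("contrast must be in (0, 0.9]")
  if (animal_length_px[1] < 3 || animal_length_px[2] > 4 ||
      animal_width_px[1] < 1 || animal_width_px[2] > 3)
    stopf("animal dimensions outside the 3-4 x 1-3 pixel envelope")
  structure(as.list(environment()), class = "wd_scene_spec")
}

#' Generate a synthetic scene with ground truth
#'
#' @param spec a [scene_spec()].
#' @return list with `scene` (a `wd_scene`) and `truth` (a `wd_points` of
#'   animal centers, `source_tag = "ground-truth"`).
#' @export
generate_scene <- function(spec) {
  built <- with_seed(spec$seed, {
    parts <- synth_parts(spec)
    list(parts = parts,
         bands = render_animals(parts$background, parts$animals, spec))
  })
  parts <- built$parts; bands <- built$bands
  scene <- new_scene(bands, pixel_size = spec$pixel_size,
                     origin = c(0, spec$height_px * spec$pixel_size),
                     crs_label = "synthetic-meters")
  w <- pixel_to_world(geotransform(scene), parts$animals$row,
                      parts$animals$col)
  list(scene = scene,
       truth = new_points(w$x, w$y, source_tag = "ground-truth"))
}

#' Generate a scene pair emulating cross-referencing against a second date
#'
#' Two scenes share an identical background and identical confuser objects;
#' animals are present only in scene A. Differencing the pair highlights
#' the moving animals while static look-alikes (bushes, mound shadows)
#' cancel — the disambiguation workflow used when labeling.
#'
#' @param spec a [scene_spec()].
#' @return list with `scene_a` (animals present), `scene_b` (reference,
#'   no animals) and `truth`.
#' @export
generate_reference_pair <- function(spec) {
  built <- with_seed(spec$seed, {
    parts <- synth_parts(spec)
    list(parts = parts,
         bands = render_animals(parts$background, parts$animals, spec))
  })
  parts <- built$parts; bands_a <- built$bands
  origin <- c(0, spec$height_px * spec$pixel_size)
  scene_a <- new_scene(bands_a, spec$pixel_size, origin,
                       crs_label = "synthetic-meters")
  scene_b <- new_scene(parts$background, spec$pixel_size, origin,
                       crs_label = "synthetic-meters")
  w <- pixel_to_world(geotransform(scene_a), parts$animals$row,
                      parts$animals$col)
  list(scene_a = scene_a, scene_b = scene_b,
       truth = new_points(w$x, w$y, source_tag = "ground-truth"))
}

#' Oracle probability map from ground truth
#'
#' Builds the probability map a perfect segmentation model would produce:
#' 3x3 blocks of high probability at every ground-truth point over a
#' low-probability background, with optional uniform noise. Used to
#' exercise post-processing and evaluation in isolation from learning.
#'
#' @param truth a `wd_points` of ground-truth animal centers.
#' @param gt geotransform of the target map.
#' @param dim integer `(height, width)` in pixels.
#' @param noise_level uniform noise amplitude in `[0, 0.5)`; 0 gives an
#'   exact 1/0 map.
#' @param block footprint edge (odd; default 3).
#' @return probability matrix.
#' @export
generate_oracle_probmap <- function(truth, gt, dim, noise_level = 0,
                                    block = 3L) {
  if (noise_level < 0 || noise_level >= 0.5)
    stopf("noise_level must be in [0, 0.5)")
  h <- dim[1]; w <- dim[2]
  p <- if (noise_level > 0)
    matrix(stats::runif(h * w, 0, noise_level), h, w) else matrix(0, h, w)
  mask <- rasterize_points(truth, gt, dim, size = block)
  hot <- which(mask == 1L)
  p[hot] <- if (noise_level > 0)
    stats::runif(length(hot), 1 - noise_level, 1) else 1
  p
}

#' Read and write scene specifications as YAML
#'
#' @param spec a [scene_spec()].
#' @param path a `.yaml` file.
#' @return `read_scene_spec()` returns a `wd_scene_spec`.
#' @export
write_scene_spec <- function(spec, path) {
  vals <- unclass(spec)
  vals$confusers <- as.list(vals$confusers)  # keep names through YAML
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' @rdname write_scene_spec
#' @export
read_scene_spec <- function(path) {
  vals <- yaml::read_yaml(path)
  vals$confusers <- unlist(vals$confusers)
  do.call(scene_spec, vals)
}

# ---- internals ---------------------------------------------------------

# everything static: background texture + confusers, plus animal centers
synth_parts <- function(spec) {
  h <- spec$height_px; w <- spec$width_px
  base_dn <- c(R = 1100, G = 1050, B = 950, NIR = 1500)
  bands <- array(0, c(h, w, 4))
  tex_px <- max(2, round(spec$background_texture_scale / spec$pixel_size))
  shared <- smooth_field(h, w, tex_px)        # common relief
  for (b in 1:4) {
    own <- smooth_field(h, w, tex_px)
    tex <- 0.7 * shared + 0.3 * own
    bands[, , b] <- base_dn[b] * (1 + 0.05 * tex) +
      stats::rnorm(h * w, 0, 0.012 * base_dn[b])
  }
  animals <- place_animals(spec)
  bands <- render_confusers(bands, spec, avoid = animals)
  bands[bands < 0] <- 0
  bands[bands > 2047] <- 2047
  list(background = bands, animals = animals)
}

# coarse gaussian grid bilinearly upsampled to h x w, values ~ N(0, 1)
smooth_field <- function(h, w, cell_px) {
  gh <- max(2, ceiling(h / cell_px) + 1)
  gw <- max(2, ceiling(w / cell_px) + 1)
  g <- matrix(stats::rnorm(gh * gw), gh, gw)
  ri <- (seq_len(h) - 1) / cell_px
  ci <- (seq_len(w) - 1) / cell_px
  r0 <- pmin(floor(ri), gh - 2); c0 <- pmin(floor(ci), gw - 2)
  fr <- ri - r0; fc <- ci - c0
  a <- g[cbind(rep(r0 + 1, w), rep(c0 + 1, each = h))]
  b <- g[cbind(rep(r0 + 2, w), rep(c0 + 1, each = h))]
  cc <- g[cbind(rep(r0 + 1, w), rep(c0 + 2, each = h))]
  d <- g[cbind(rep(r0 + 2, w), rep(c0 + 2, each = h))]
  fr_m <- matrix(fr, h, w); fc_m <- matrix(fc, h, w, byrow = TRUE)
  matrix(a, h, w) * (1 - fr_m) * (1 - fc_m) +
    matrix(b, h, w) * fr_m * (1 - fc_m) +
    matrix(cc, h, w) * (1 - fr_m) * fc_m +
    matrix(d, h, w) * fr_m * fc_m
}

place_animals <- function(spec) {
  n <- spec$n_animals
  h <- spec$height_px; w <- spec$width_px
  if (n == 0) return(data.frame(row = integer(), col = integer()))
  margin <- 3
  min_sep <- switch(spec$aggregation, scattered = spec$min_sep_px,
                    linear = 2.5, clustered = 2.5)
  rows <- numeric(0); cols <- numeric(0)
  propose <- switch(
    spec$aggregation,
    scattered = function(k) cbind(stats::runif(k, margin, h - 1 - margin),
                                  stats::runif(k, margin, w - 1 - margin)),
    clustered = local({
      par_r <- stats::runif(spec$cluster_parents, margin, h - 1 - margin)
      par_c <- stats::runif(spec$cluster_parents, margin, w - 1 - margin)
      spread <- spec$cluster_spread / spec$pixel_size
      function(k) {
        p <- sample.int(spec$cluster_parents, k, replace = TRUE)
        cbind(par_r[p] + stats::rnorm(k, 0, spread),
              par_c[p] + stats::rnorm(k, 0, spread))
      }
    }),
    linear = local({
      # random polyline crossing the scene, jittered placement along it
      nseg <- 4
      vx <- stats::runif(nseg + 1, margin, w - 1 - margin)
      vy <- stats::runif(nseg + 1, margin, h - 1 - margin)
      function(k) {
        t <- stats::runif(k, 0, nseg)
        s <- pmin(floor(t), nseg - 1); f <- t - s
        cbind(vy[s + 1] * (1 - f) + vy[s + 2] * f + stats::rnorm(k, 0, 2),
              vx[s + 1] * (1 - f) + vx[s + 2] * f + stats::rnorm(k, 0, 2))
      }
    }))
  attempts <- 0L
  while (length(rows) < n) {
    attempts <- attempts + 1L
    if (attempts > 400L * n)
      stopf("cannot place %d animals without overlap in a %dx%d scene",
            n, h, w)
    cand <- propose(1L)
    r <- round(cand[1]); c <- round(cand[2])
    if (r < margin || r > h - 1 - margin || c < margin || c > w - 1 - margin)
      next
    if (length(rows) &&
        min(pmax(abs(rows - r), abs(cols - c))) < min_sep) next
    rows <- c(rows, r); cols <- c(cols, c)
  }
  data.frame(row = as.integer(rows), col = as.integer(cols))
}

render_animals <- function(bands, animals, spec) {
  if (!nrow(animals)) return(bands)
  h <- dim(bands)[1]; w <- dim(bands)[2]
  # drop factors per band: NIR contrast slightly weaker than visible
  band_f <- c(1, 1, 1, 0.8)
  for (i in seq_len(nrow(animals))) {
    r <- animals$row[i]; c <- animals$col[i]
    len <- sample(spec$animal_length_px[1]:spec$animal_length_px[2], 1)
    wid <- sample(spec$animal_width_px[1]:spec$animal_width_px[2], 1)
    nd <- sample(spec$dark_center_px[1]:spec$dark_center_px[2], 1)
    th <- stats::runif(1, 0, pi)
    fp <- ellipse_footprint(len, wid, th)
    for (j in seq_len(nrow(fp))) {
      rr <- r + fp$dr[j]; cc <- c + fp$dc[j]
      if (rr < 0 || rr >= h || cc < 0 || cc >= w) next
      drop <- spec$contrast * fp$core[j]
      bands[rr + 1, cc + 1, ] <- bands[rr + 1, cc + 1, ] *
        (1 - drop * band_f)
    }
    # darker central pixels along the major axis
    dirs <- rbind(c(0, 0), c(round(sin(th)), round(cos(th))))
    for (j in seq_len(nd)) {
      rr <- r + dirs[j, 1]; cc <- c + dirs[j, 2]
      if (rr < 0 || rr >= h || cc < 0 || cc >= w) next
      bands[rr + 1, cc + 1, ] <- bands[rr + 1, cc + 1, ] * 0.55
    }
  }
  bands
}

# pixel offsets covered by a rotated ellipse of given length/width (pixels)
ellipse_footprint <- function(len, wid, theta) {
  half <- ceiling(len / 2)
  off <- expand.grid(dr = -half:half, dc = -half:half)
  u <- off$dc * cos(theta) + off$dr * sin(theta)
  v <- -off$dc * sin(theta) + off$dr * cos(theta)
  a <- len / 2; b <- max(wid / 2, 0.5)
  inside <- (u / a)^2 + (v / b)^2 <= 1.0001
  inside[off$dr == 0 & off$dc == 0] <- TRUE
  core <- 1 - 0.3 * ((u / a)^2 + (v / b)^2)   # soft edge
  data.frame(dr = off$dr[inside], dc = off$dc[inside],
             core = pmax(core[inside], 0.4))
}

render_confusers <- function(bands, spec, avoid) {
  h <- dim(bands)[1]; w <- dim(bands)[2]
  cf <- function(nm) {
    v <- spec$confusers[nm]
    if (length(v) != 1 || is.na(v)) 0L else as.integer(v)
  }
  mult <- function(rr, cc, f) {
    ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    for (b in 1:4)
      bands[cbind(rr[ok], cc[ok], b)] <<- bands[cbind(rr[ok], cc[ok], b)] *
        f[b]
  }
  free_spot <- function(clearance) {
    for (try in 1:50) {
      r <- round(stats::runif(1, 6, h - 6)); c <- round(stats::runif(1, 6, w - 6))
      if (!nrow(avoid) ||
          min((avoid$row - r)^2 + (avoid$col - c)^2) >= clearance^2)
        return(c(r, c))
    }
    NULL
  }
  for (i in seq_len(cf("bush"))) {
    s <- free_spot(8); if (is.null(s)) next
    rad <- stats::runif(1, 2, 4)
    off <- expand.grid(dr = -4:4, dc = -4:4)
    keep <- off$dr^2 + off$dc^2 <= rad^2
    mult(s[1] + off$dr[keep] + 1, s[2] + off$dc[keep] + 1,
         c(0.8, 0.75, 0.8, 1.15))   # dark visible, bright NIR: vegetation
  }
  for (i in seq_len(cf("mound_shadow"))) {
    s <- free_spot(8); if (is.null(s)) next
    len <- round(stats::runif(1, 6, 10)); th <- stats::runif(1, 0, pi)
    t <- seq(0, len - 1)
    for (lat in -1:1) {
      rr <- round(s[1] + t * sin(th) + lat * cos(th)) + 1
      cc <- round(s[2] + t * cos(th) - lat * sin(th)) + 1
      mult(rr, cc, rep(0.5, 4))
    }
  }
  for (i in seq_len(cf("road"))) {
    r0 <- stats::runif(1, 0.2 * h, 0.8 * h); slope <- stats::runif(1, -0.3, 0.3)
    for (lat in 0:2) {
      cc <- seq_len(w)
      rr <- round(r0 + slope * cc) + lat
      mult(rr, cc, c(1.25, 1.2, 1.25, 1.1))   # bare soil: brighter
    }
  }
  for (i in seq_len(cf("river"))) {
    c0 <- stats::runif(1, 0.3 * w, 0.7 * w)
    amp <- stats::runif(1, 5, 15); per <- stats::runif(1, 60, 120)
    for (lat in -3:3) {
      rr <- seq_len(h)
      cc <- round(c0 + amp * sin(2 * pi * rr / per)) + lat
      mult(rr, cc, c(0.6, 0.65, 0.7, 0.35))   # water: dark, very dark NIR
    }
  }
  bands
}
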
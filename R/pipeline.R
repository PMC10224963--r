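#' Command-line pipeline entry point
#'
#' Dispatches the subcommands of the `wildetect` command-line tool
#' (installed at `inst/cli/wildetect.R`): `simulate`, `prepare`, `train`,
#' `predict`, `evaluate`, `density` and `count`. Options come from a YAML
#' configuration file plus `--key value` overrides; every run writes a
#' JSON manifest (config, seed, package version, outputs) next to its
#' artifacts so any output can be regenerated from its manifest alone.
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return exit status, 0 on success (invisibly).
#' @export
wd_cli <- function(args) {
  usage <- paste(
    "usage: wildetect <command> [--config file.yaml] [--key value ...]",
    "commands:",
    "  simulate  generate a synthetic scene + ground truth",
    "            (--out dir, --seed, --n_animals, --width_px, --height_px,",
    "             --aggregation)",
    "  prepare   grid a scene and rasterize labels",
    "            (--scene tif, --points csv, --out dir, --patch_px)",
    "  train     train the K-fold U-Net ensemble on prepared patches",
    "            (--data dir, --out dir, --k, --epochs, --seed, --preset)",
    "  predict   detect animals in a scene with a trained ensemble",
    "            (--scene tif, --model dir, --out dir)",
    "  evaluate  score detections against reference points",
    "            (--pred csv, --ref csv, --pixel_size, --out dir)",
    "  density   hotspot raster + per-km2 histogram from points",
    "            (--points csv, --out dir, --cell_size, --radius)",
    "  count     census count with 95% CI from repeated run totals",
    "            (--counts '100,104,98', --out dir)",
    sep = "\n")
  if (!length(args) || args[1] %in% c("-h", "--help")) {
    message(usage); return(invisible(0L))
  }
  cmd <- args[1]
  opt <- parse_cli_opts(args[-1])
  if (!is.null(opt$config)) {
    cfg <- yaml::read_yaml(opt$config)
    for (k in setdiff(names(cfg), names(opt))) opt[[k]] <- cfg[[k]]
  }
  out_dir <- opt$out %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(opt$seed %||% 1L)
  handler <- switch(cmd,
    simulate = cli_simulate, prepare = cli_prepare, train = cli_train,
    predict = cli_predict, evaluate = cli_evaluate, density = cli_density,
    count = cli_count,
    { message("unknown command: ", cmd, "\n", usage); return(invisible(2L)) })
  outputs <- handler(opt, out_dir, seed)
  manifest <- list(command = cmd, options = opt, seed = seed,
                   package_version = as.character(utils::packageVersion("wildetect")),
                   outputs = outputs, timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(0L)
}

parse_cli_opts <- function(args) {
  opt <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!grepl("^--", args[i])) stopf("unexpected argument '%s'", args[i])
    key <- sub("^--", "", args[i])
    if (i == length(args) || grepl("^--", args[i + 1])) {
      opt[[key]] <- TRUE; i <- i + 1L
    } else {
      opt[[key]] <- args[i + 1]; i <- i + 2L
    }
  }
  opt
}

cli_simulate <- function(opt, out_dir, seed) {
  spec <- scene_spec(
    width_px = as.integer(opt$width_px %||% 336L),
    height_px = as.integer(opt$height_px %||% 336L),
    n_animals = as.integer(opt$n_animals %||% 50L),
    aggregation = opt$aggregation %||% "scattered",
    seed = seed)
  sim <- generate_scene(spec)
  write_scene(sim$scene, file.path(out_dir, "scene.tif"))
  write_points(sim$truth, file.path(out_dir, "truth.csv"))
  list(scene = "scene.tif", truth = "truth.csv",
       n_animals = nrow(sim$truth))
}

cli_prepare <- function(opt, out_dir, seed) {
  scene <- load_scene(opt$scene, require_bands = 4)
  patch_px <- as.integer(opt$patch_px %||% 336L)
  grid <- build_grid(scene, patch_px)
  utils::write.csv(grid, file.path(out_dir, "grid.csv"), row.names = FALSE)
  outs <- list(grid = "grid.csv", n_cells = nrow(grid))
  if (!is.null(opt$points)) {
    pts <- read_points(opt$points)
    mask <- rasterize_points(pts, geotransform(scene), scene_dim(scene))
    tiff::writeTIFF(mask + 0, file.path(out_dir, "mask.tif"),
                    bits.per.sample = 8L)
    outs$mask <- "mask.tif"
    outs$n_positive_px <- sum(mask)
  }
  outs
}

cli_train <- function(opt, out_dir, seed) {
  data_dir <- opt$data
  scene <- load_scene(file.path(data_dir, "scene.tif"), require_bands = 4)
  truth <- read_points(file.path(data_dir, "truth.csv"))
  preset <- opt$preset %||% "small"
  mcfg <- if (preset == "small") unet_config_small() else unet_config()
  patch_px <- mcfg$input_size[1]
  grid <- build_grid(scene, patch_px)
  grid <- grid[grid$full, ]
  pairs <- lapply(seq_len(nrow(grid)), function(i) {
    p <- extract_patch(scene, grid[i, ], pad = TRUE, patch_px = patch_px)
    list(image = normalize_patch(p),
         mask = rasterize_points(truth, geotransform(p), c(patch_px, patch_px)))
  })
  K <- as.integer(opt$k %||% 3L)
  tcfg <- train_config(epochs = as.integer(opt$epochs %||% 20L),
                       seed = seed)
  ens <- train_ensemble(pairs, mcfg, tcfg,
                        ensemble_config(K = K, seed = seed))
  for (i in seq_along(ens$models))
    save_unet(ens$models[[i]], file.path(out_dir, sprintf("model_%02d.json", i)))
  jsonlite::write_json(
    list(K = K, preset = preset,
         members = sprintf("model_%02d.json", seq_len(K))),
    file.path(out_dir, "ensemble.json"), auto_unbox = TRUE)
  list(ensemble = "ensemble.json", K = K)
}

cli_predict <- function(opt, out_dir, seed) {
  scene <- load_scene(opt$scene, require_bands = 4)
  man <- jsonlite::read_json(file.path(opt$model, "ensemble.json"),
                             simplifyVector = TRUE)
  models <- lapply(man$members, function(f)
    load_unet(file.path(opt$model, f)))
  dcfg <- detect_config(kmeans_seed = seed)
  det <- detect_scene(models, scene, dcfg,
                      patch_px = models[[1]]$config$input_size[1])
  write_points(det, file.path(out_dir, "detections.csv"))
  write_points(det, file.path(out_dir, "detections.geojson"))
  list(detections = "detections.csv", n_detected = nrow(det))
}

cli_evaluate <- function(opt, out_dir, seed) {
  pred <- read_points(opt$pred)
  ref <- read_points(opt$ref)
  radius <- matching_radius(as.numeric(opt$pixel_size %||% 0.5))
  m <- match_points(pred, ref, radius)
  mt <- compute_metrics(m)
  jsonlite::write_json(mt, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  list(metrics = "metrics.json", f1 = mt$f1)
}

cli_density <- function(opt, out_dir, seed) {
  pts <- read_points(opt$points)
  pad <- as.numeric(opt$radius %||% 500)
  extent <- c(min(pts$x) - pad, min(pts$y) - pad,
              max(pts$x) + pad, max(pts$y) + pad)
  dm <- point_density(pts, extent,
                      cell_size = as.numeric(opt$cell_size %||% 100),
                      radius = as.numeric(opt$radius %||% 500))
  write_density(dm, file.path(out_dir, "density.tif"))
  hist <- density_histogram(pts, extent)
  utils::write.csv(hist, file.path(out_dir, "histogram.csv"),
                   row.names = FALSE)
  list(density = "density.tif", histogram = "histogram.csv",
       max_density_per_km2 = max(dm$values))
}

cli_count <- function(opt, out_dir, seed) {
  counts <- as.numeric(strsplit(opt$counts, ",")[[1]])
  est <- count_with_ci(counts)
  jsonlite::write_json(est, file.path(out_dir, "count.json"),
                       auto_unbox = TRUE, digits = NA)
  list(count = "count.json", mean_count = est$mean_count)
}
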
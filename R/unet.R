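#' U-Net architecture configuration
#'
#' A symmetric encoder-decoder with skip connections: `depth` levels of two
#' 3x3 same-padded convolutions (ReLU) followed by 2x2 max pooling, a
#' two-convolution bottleneck, and a mirrored decoder that upsamples
#' (nearest-neighbor + 3x3 convolution), concatenates the encoder feature
#' map of matching resolution and applies two further convolutions. A final
#' 1x1 convolution with a sigmoid yields the per-pixel presence
#' probability. Filters start at `base_filters` and double per level.
#' Weights use He-normal initialization.
#'
#' `unet_config_small()` is a reduced preset (depth 3, 8 base filters,
#' 96x96 input) sized so that a full ensemble study on synthetic scenes
#' runs in minutes on a single CPU core; the default configuration mirrors
#' the full-scale setting (depth 4, 64 filters, 336x336 input).
#'
#' @param depth number of pooling levels (>= 2); the input edge must be
#'   divisible by `2^depth`.
#' @param base_filters filters of the first level.
#' @param input_size integer `(height, width, bands)`.
#' @param dropout_rate dropout applied to the bottleneck output during
#'   training (default 0).
#' @return list of class `wd_unet_config`.
#' @export
unet_config <- function(depth = 4L, base_filters = 64L,
                        input_size = c(336L, 336L, 4L), dropout_rate = 0) {
  if (depth < 2) stopf("depth must be >= 2")
  if (any(input_size[1:2] %% 2^depth != 0))
    stopf("input size %dx%d not divisible by 2^%d", input_size[1],
          input_size[2], depth)
  if (dropout_rate < 0 || dropout_rate >= 1) stopf("bad dropout rate")
  structure(list(depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 input_size = as.integer(input_size),
                 dropout_rate = dropout_rate, init_scheme = "he_normal"),
            class = "wd_unet_config")
}

#' @rdname unet_config
#' @export
unet_config_small <- function() {
  unet_config(depth = 3L, base_filters = 8L, input_size = c(96L, 96L, 4L))
}

#' Training configuration
#'
#' Defaults follow the full-scale recipe: Adam with initial learning rate
#' 1e-4, reduced by a factor of 0.33 when the validation loss has not
#' improved for 20 epochs; batch size 12; 120 epochs; Tversky loss with
#' false-negative weight 0.9 and false-positive weight 0.1 (the asymmetry
#' that counters the <1% positive-pixel class imbalance by prioritizing
#' recall of animal pixels); the checkpoint with the smallest validation
#' loss across epochs is kept.
#'
#' @param fp_weight,fn_weight Tversky penalty weights for false positives
#'   and false negatives; must sum to 1.
#' @param smooth additive smoothing constant of the Tversky ratio.
#' @param learning_rate initial Adam learning rate.
#' @param plateau_factor multiplicative learning-rate decay on plateau.
#' @param plateau_patience epochs without validation improvement before the
#'   decay triggers.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param seed integer seed driving weight initialization and shuffling.
#' @param warmup_epochs train the first epochs with recall-heavy weights
#'   (`warmup_fn_weight`) before switching to the target weights; under
#'   heavy class imbalance this keeps early optimization out of the
#'   all-background minimum. Validation (and checkpoint selection) always
#'   uses the target weights. Default 0 (no warmup).
#' @param warmup_fn_weight false-negative weight used during warmup.
#' @return list of class `wd_train_config`.
#' @export
train_config <- function(fp_weight = 0.1, fn_weight = 0.9, smooth = 1.0,
                         learning_rate = 1e-4, plateau_factor = 0.33,
                         plateau_patience = 20L, batch_size = 12L,
                         epochs = 120L, seed = 1L, warmup_epochs = 0L,
                         warmup_fn_weight = 0.9) {
  if (abs(fp_weight + fn_weight - 1) > 1e-9)
    stopf("fp_weight + fn_weight must equal 1")
  if (min(fp_weight, fn_weight, smooth, learning_rate, plateau_factor) < 0)
    stopf("rates must be non-negative")
  if (warmup_fn_weight <= 0 || warmup_fn_weight >= 1)
    stopf("warmup_fn_weight must be in (0, 1)")
  structure(list(fp_weight = fp_weight, fn_weight = fn_weight,
                 smooth = smooth, learning_rate = learning_rate,
                 plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 warmup_epochs = as.integer(warmup_epochs),
                 warmup_fn_weight = warmup_fn_weight),
            class = "wd_train_config")
}

#' Build an untrained U-Net
#'
#' @param config a [unet_config()].
#' @param seed integer seed for He-normal weight initialization; two builds
#'   with the same seed have identical weights.
#' @return object of class `wd_unet`: `config` plus the weight list.
#' @export
build_unet <- function(config = unet_config(), seed = 1L) {
  w <- unet_init_cpp(config$depth, config$base_filters,
                     config$input_size[3], as.integer(seed))
  structure(list(config = config, weights = w, history = NULL),
            class = "wd_unet")
}

#' @export
print.wd_unet <- function(x, ...) {
  np <- sum(vapply(x$weights, length, numeric(1)))
  cat(sprintf("<wd_unet> depth %d, %d base filters, input %dx%dx%d, %s parameters%s\n",
              x$config$depth, x$config$base_filters, x$config$input_size[1],
              x$config$input_size[2], x$config$input_size[3],
              format(np, big.mark = ","),
              if (is.null(x$history)) " (untrained)" else ""))
  invisible(x)
}

#' Tversky loss
#'
#' Asymmetric generalization of the Dice loss with separate penalty
#' weights for false positives and false negatives, computed on soft
#' counts: `TP = sum(p t)`, `FP = sum(p (1 - t))`, `FN = sum((1 - p) t)`,
#' and
#' `loss = 1 - (TP + smooth) / (TP + fp_weight FP + fn_weight FN + smooth)`.
#' At weights (0.5, 0.5) it reduces to the Dice loss; weighting false
#' negatives more steers the model towards recalling rare positive pixels.
#'
#' @param pred probability array in `[0, 1]`.
#' @param target binary array of the same shape.
#' @param fp_weight,fn_weight penalty weights summing to 1.
#' @param smooth additive smoothing constant (default 1).
#' @return scalar loss in `[0, 1]`.
#' @export
tversky_loss <- function(pred, target, fp_weight = 0.1, fn_weight = 0.9,
                         smooth = 1.0) {
  if (!all(dim(pred) %||% length(pred) == (dim(target) %||% length(target))))
    stopf("pred and target shapes differ")
  if (abs(fp_weight + fn_weight - 1) > 1e-9)
    stopf("fp_weight + fn_weight must equal 1")
  tp <- sum(pred * target)
  fp <- sum(pred * (1 - target))
  fn <- sum((1 - pred) * target)
  1 - (tp + smooth) / (tp + fp_weight * fp + fn_weight * fn + smooth)
}

#' Train one base U-Net
#'
#' Minimizes the mean per-sample Tversky loss with Adam; the learning rate
#' decays by `plateau_factor` after `plateau_patience` epochs without
#' validation improvement, and the checkpoint with the smallest validation
#' loss among all epochs is returned. One integer seed drives weight
#' initialization and shuffling, so identical seeds and data reproduce the
#' history exactly (single-threaded).
#'
#' @param train_pairs,val_pairs non-empty lists of `list(image, mask)`
#'   pairs; images are normalized `H x W x B` arrays, masks binary
#'   matrices.
#' @param mconfig a [unet_config()].
#' @param tconfig a [train_config()].
#' @param augment expand the training set with the flip/rotation variants
#'   of [augment_pair()].
#' @param max_restarts under heavy class imbalance the Tversky loss has an
#'   all-background local minimum; if the best validation loss never gets
#'   clearly below the analytic all-background baseline the run is
#'   restarted with a derived seed, at most this many times (default 4).
#'   Schedules shorter than 10 epochs are treated as smoke runs and never
#'   gated.
#' @return a trained `wd_unet` whose `history` is a data.frame with
#'   per-epoch `train_loss`, `val_loss` and `lr`; the seed that produced
#'   the returned model is recorded in `tconfig$seed`.
#' @export
train_base_model <- function(train_pairs, val_pairs, mconfig = unet_config(),
                             tconfig = train_config(), augment = TRUE,
                             max_restarts = 4L) {
  if (!length(train_pairs) || !length(val_pairs))
    stopf("training and validation sets must be non-empty")
  # mean validation loss of the trivial all-background prediction
  collapse_baseline <- mean(vapply(val_pairs, function(p)
    1 - tconfig$smooth / (tconfig$fn_weight * sum(p$mask) + tconfig$smooth),
    numeric(1)))
  # the gate only makes sense when a run had a realistic chance to
  # converge: schedules under 10 epochs (smoke runs) and all-empty
  # validation masks are trained once, ungated
  if (collapse_baseline <= 0 || tconfig$epochs < 10L)
    return(train_base_model_once(train_pairs, val_pairs, mconfig, tconfig,
                                 augment))
  best <- NULL
  for (attempt in 0:max_restarts) {
    # a run still at ~the all-background loss by epoch 6 will not recover;
    # aborting it early makes restarts cheap
    fit <- train_base_model_once(train_pairs, val_pairs, mconfig, tconfig,
                                 augment,
                                 abort_threshold = 0.9 * collapse_baseline,
                                 abort_epoch = if (collapse_baseline > 0 &&
                                                   tconfig$epochs > 6L)
                                   6L else 0L)
    if (is.null(best) ||
        min(fit$history$val_loss) < min(best$history$val_loss)) best <- fit
    # a converged model sits far below every failure mode (all-background,
    # all-foreground, unstructured output), all of which stay near the
    # all-background baseline
    if (collapse_baseline <= 0 ||
        min(fit$history$val_loss) < 0.5 * collapse_baseline) return(fit)
    warning(sprintf(
      "training failed to converge (best validation loss %.3f vs all-background %.3f; seed %d); %s",
      min(fit$history$val_loss), collapse_baseline, tconfig$seed,
      if (attempt < max_restarts) "restarting with a new seed"
      else "returning the best attempt"))
    tconfig$seed <- derive_seed(tconfig$seed, 7919L)
  }
  best
}

train_base_model_once <- function(train_pairs, val_pairs, mconfig, tconfig,
                                  augment, abort_threshold = 0,
                                  abort_epoch = 0L) {
  if (augment)
    train_pairs <- unlist(lapply(train_pairs, augment_pair),
                          recursive = FALSE, use.names = FALSE)
  d <- mconfig$input_size
  check_pair <- function(p) {
    if (!all(dim(p$image) == d) || !all(dim(p$mask) == d[1:2]))
      stopf("pair dimensions do not match model input %dx%dx%d",
            d[1], d[2], d[3])
  }
  lapply(train_pairs, check_pair); lapply(val_pairs, check_pair)
  n_tr <- length(train_pairs); n_va <- length(val_pairs)
  imgs <- array(0, c(d[1], d[2], d[3], n_tr + n_va))
  msks <- array(0, c(d[1], d[2], n_tr + n_va))
  for (i in seq_len(n_tr)) {
    imgs[, , , i] <- train_pairs[[i]]$image
    msks[, , i] <- train_pairs[[i]]$mask
  }
  for (i in seq_len(n_va)) {
    imgs[, , , n_tr + i] <- val_pairs[[i]]$image
    msks[, , n_tr + i] <- val_pairs[[i]]$mask
  }
  fit <- unet_train_cpp(imgs, msks, seq_len(n_tr), n_tr + seq_len(n_va),
                        mconfig$depth, mconfig$base_filters,
                        mconfig$dropout_rate,
                        tconfig$learning_rate, tconfig$fp_weight,
                        tconfig$fn_weight, tconfig$smooth,
                        tconfig$batch_size, tconfig$epochs,
                        tconfig$plateau_factor, tconfig$plateau_patience,
                        tconfig$seed, abort_threshold, as.integer(abort_epoch),
                        tconfig$warmup_epochs %||% 0L,
                        tconfig$warmup_fn_weight %||% 0.9)
  structure(list(config = mconfig, weights = fit$weights,
                 history = data.frame(epoch = seq_along(fit$val_loss),
                                      train_loss = fit$train_loss,
                                      val_loss = fit$val_loss, lr = fit$lr),
                 best_epoch = fit$best_epoch, tconfig = tconfig),
            class = "wd_unet")
}

#' Sweep the Tversky false-negative weight
#'
#' Trains one base model per candidate `fn_weight` (with
#' `fp_weight = 1 - fn_weight`) and scores each on validation tiles with
#' the full detection chain, returning per-weight point-level precision,
#' recall and F1. This is the sensitivity analysis used to pick the
#' penalty asymmetry; the full-scale default is
#' `fn_weight = 0.9`.
#'
#' @param train_pairs,val_tiles training pairs and validation tiles; each
#'   validation tile is a `list(image, truth, gt)`.
#' @param mconfig,tconfig model and training configuration (the weight
#'   fields of `tconfig` are overridden per candidate).
#' @param fn_weights candidate false-negative weights in (0, 1).
#' @param dconfig detection configuration used for scoring.
#' @param radius matching radius in meters.
#' @param augment expand training folds with flips/rotation.
#' @return data.frame with one row per weight: `fn_weight`, `precision`,
#'   `recall`, `f1`, `val_loss`.
#' @export
sweep_tversky_weights <- function(train_pairs, val_tiles, mconfig, tconfig,
                                  fn_weights = c(0.01, seq(0.1, 0.9, 0.1),
                                                 0.99),
                                  dconfig = detect_config(),
                                  radius = matching_radius(0.5),
                                  augment = TRUE) {
  rows <- lapply(fn_weights, function(bw) {
    tcfg <- tconfig
    tcfg$fn_weight <- bw
    tcfg$fp_weight <- 1 - bw
    fit <- train_base_model(train_pairs,
                            lapply(val_tiles, function(t)
                              list(image = t$image,
                                   mask = rasterize_points(
                                     t$truth, t$gt, dim(t$image)[1:2]))),
                            mconfig, tcfg, augment = augment)
    tp <- fp <- fn <- 0L
    for (t in val_tiles) {
      pm <- normalize_probmap(predict_patch(fit, t$image))
      det <- detect_from_probmap(pm, t$gt, dconfig)
      m <- match_points(det, t$truth, radius)
      tp <- tp + nrow(m$tp_pairs); fp <- fp + length(m$fp)
      fn <- fn + length(m$fn)
    }
    mt <- compute_metrics(tp = tp, fp = fp, fn = fn)
    data.frame(fn_weight = bw, precision = mt$precision,
               recall = mt$recall, f1 = mt$f1,
               val_loss = min(fit$history$val_loss))
  })
  do.call(rbind, rows)
}

#' Predict the probability map of one patch
#'
#' @param model a `wd_unet`.
#' @param patch normalized `H x W x B` array matching the model input size
#'   (a `wd_scene` patch is normalized automatically).
#' @return probability matrix `H x W` with values in `[0, 1]`.
#' @export
predict_patch <- function(model, patch) {
  if (is_scene(patch)) patch <- normalize_patch(patch)
  d <- model$config$input_size
  if (!all(dim(patch) == d))
    stopf("patch is %s; model expects %dx%dx%d",
          paste(dim(patch), collapse = "x"), d[1], d[2], d[3])
  unet_predict_cpp(array(patch, c(dim(patch), 1L)), model$weights,
                   model$config$depth, model$config$base_filters)[, , 1]
}

#' Save / load a trained model
#'
#' Checkpoints are JSON: configuration plus flattened weight tensors, a
#' plain-text format stable across platforms.
#'
#' @param model a `wd_unet`.
#' @param path file path ending in `.json`.
#' @return `load_unet()` returns a `wd_unet`.
#' @export
save_unet <- function(model, path) {
  obj <- list(config = unclass(model$config),
              weights = lapply(model$weights, function(w)
                list(dim = dim(w) %||% length(w), data = as.numeric(w))),
              best_epoch = model$best_epoch)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_unet
#' @export
load_unet <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  cfg <- do.call(unet_config, obj$config[c("depth", "base_filters",
                                           "input_size", "dropout_rate")])
  ws <- lapply(obj$weights, function(w) {
    if (length(w$dim) > 1) array(w$data, unlist(w$dim)) else as.numeric(w$data)
  })
  structure(list(config = cfg, weights = ws,
                 best_epoch = obj$best_epoch %||% NA, history = NULL),
            class = "wd_unet")
}
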
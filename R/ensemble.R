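#' Ensemble configuration
#'
#' @param K number of folds / base models (default 10).
#' @param rescale_threshold base-model maps are min-max rescaled to `[0, 1]`
#'   only when their maximum exceeds this gate (default 0.05); essentially
#'   empty maps are left untouched rather than having noise amplified.
#' @param seed integer seed driving fold assignment and member training.
#' @return list of class `wd_ensemble_config`.
#' @export
ensemble_config <- function(K = 10L, rescale_threshold = 0.05, seed = 1L) {
  if (K < 2) stopf("K must be >= 2")
  if (rescale_threshold <= 0 || rescale_threshold >= 1)
    stopf("rescale_threshold must be in (0, 1)")
  structure(list(K = as.integer(K), rescale_threshold = rescale_threshold,
                 seed = as.integer(seed)),
            class = "wd_ensemble_config")
}

#' Min-max rescale a probability map
#'
#' If the map's maximum exceeds `threshold` the map is rescaled to span
#' `[0, 1]` (`(p - min) / (max - min)`); otherwise it is returned
#' unchanged. A constant map above the gate carries no detection evidence
#' and is zeroed with a warning. Rescaling is applied per inference window.
#'
#' @param p probability matrix in `[0, 1]`.
#' @param threshold rescale gate, default 0.05.
#' @return rescaled matrix.
#' @export
normalize_probmap <- function(p, threshold = 0.05) {
  mx <- max(p)
  if (mx <= threshold) return(p)
  mn <- min(p)
  if (mx == mn) {
    warning("constant probability map above the rescale gate; zeroed")
    return(matrix(0, nrow(p), ncol(p)))
  }
  (p - mn) / (mx - mn)
}

#' Fuse base-model probability maps
#'
#' Element-wise mean of the (already normalized) member maps; the ensemble
#' prediction.
#'
#' @param maps list of >= 1 equal-shape probability matrices.
#' @return matrix of the same shape.
#' @export
fuse_probmaps <- function(maps) {
  if (!length(maps)) stopf("need >= 1 map")
  d <- dim(maps[[1]])
  for (m in maps) if (!all(dim(m) == d)) stopf("map shapes differ")
  Reduce(`+`, maps) / length(maps)
}

#' Train the K-fold U-Net ensemble
#'
#' Splits the training pairs into K folds; base model `i` is trained on all
#' folds but `i` and validated (checkpoint selection, plateau schedule) on
#' fold `i`. The member with the lowest validation loss epoch is kept for
#' each fold. At inference the members' maps are min-max rescaled and
#' averaged ([normalize_probmap()], [fuse_probmaps()]).
#'
#' @param pairs list of training pairs, each `list(image, mask)` with
#'   `image` a normalized `H x W x B` array and `mask` a binary matrix.
#' @param mconfig a [unet_config()].
#' @param tconfig a [train_config()]; each member trains with a seed
#'   derived from `econfig$seed` and its fold index.
#' @param econfig an [ensemble_config()].
#' @param augment expand each training fold with flips/rotation
#'   ([augment_pair()]).
#' @return list of class `wd_ensemble`: `models` (list of `wd_unet`),
#'   `folds` (fold assignment data.frame), `econfig`.
#' @export
train_ensemble <- function(pairs, mconfig, tconfig,
                           econfig = ensemble_config(), augment = TRUE) {
  folds <- split_folds(seq_along(pairs), K = econfig$K, seed = econfig$seed)
  models <- vector("list", econfig$K)
  for (k in seq_len(econfig$K) - 1L) {
    tr <- which(folds$fold != k)
    va <- which(folds$fold == k)
    tcfg <- tconfig
    tcfg$seed <- derive_seed(econfig$seed, k + 1L)
    models[[k + 1L]] <- train_base_model(pairs[tr], pairs[va], mconfig, tcfg,
                                         augment = augment)
  }
  structure(list(models = models, folds = folds, econfig = econfig),
            class = "wd_ensemble")
}

#' @export
print.wd_ensemble <- function(x, ...) {
  cat(sprintf("<wd_ensemble> %d base models (K-fold)\n", length(x$models)))
  invisible(x)
}
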
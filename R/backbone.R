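# Tile-level classifier / feature-extractor contract. The model exposes
# two views of the same forward state: extract_features() returns the
# backbone feature vector per tile and predict_tiles() applies the
# classifier head to those features, so head(features) reproduces the
# probabilities exactly.
#
# Two configurations are provided. The reference configuration mirrors a
# 34-layer residual network with a 512-dimensional feature vector; it
# defines the analytic contracts (feature lengths, the 7 x 512 = 3584
# slide vector) but ships no weights. The runnable "tiny" configuration
# pairs a fixed, deterministic texture-descriptor trunk (16 pooled
# colour/darkness/edge statistics per tile) with a trainable dense head
# optimised by the differentiable QWK loss; it is the CPU-scale stand-in
# that exercises the training pipeline end to end.

#' Backbone configuration
#'
#' @param architecture `"tiny"` (runnable descriptor trunk + dense head)
#'   or `"resnet34"` (reference contract: feature_dim 512, no bundled
#'   weights).
#' @param feature_dim Backbone feature length F.
#' @param K Number of ordered output classes.
#' @param hidden Hidden width of the tiny head.
#' @param pretrained Whether reference weights would be loaded from
#'   natural-image pretraining (flag only; default off).
#' @return Object of class `pathomil_backbone_config`.
#' @export
backbone_config <- function(architecture = c("tiny", "resnet34"),
                            feature_dim = NULL, K = 3L, hidden = 16L,
                            pretrained = FALSE) {
  architecture <- match.arg(architecture)
  if (is.null(feature_dim)) {
    feature_dim <- if (architecture == "resnet34") 512L else 16L
  }
  structure(list(architecture = architecture,
                 feature_dim = as.integer(feature_dim),
                 K = as.integer(K), hidden = as.integer(hidden),
                 pretrained = isTRUE(pretrained)),
            class = "pathomil_backbone_config")
}

#' Training hyper-parameters
#'
#' Defaults follow the adopted training recipe: adaptive-moment
#' optimiser, learning rate 6e-6, weight decay 3e-4, training batch 32,
#' inference batch 256, 5 supervised and 30 weakly supervised epochs.
#' The tiny descriptor-trunk backbone trains its dense head well at much
#' larger learning rates, so synthetic experiments override `lr`.
#'
#' @param lr Learning rate.
#' @param weight_decay L2 penalty coefficient.
#' @param batch_size Training mini-batch size.
#' @param infer_batch Inference batch size.
#' @param supervised_epochs,weak_epochs Epoch counts for the two stages.
#' @param val_fraction Held-out fraction for per-epoch QWK model
#'   selection.
#' @param seed RNG seed.
#' @return Object of class `pathomil_train_config`.
#' @export
train_config <- function(lr = 6e-6, weight_decay = 3e-4, batch_size = 32L,
                         infer_batch = 256L, supervised_epochs = 5L,
                         weak_epochs = 30L, val_fraction = 0.15,
                         seed = 1L) {
  stopifnot(lr > 0, weight_decay >= 0, batch_size >= 1, infer_batch >= 1,
            supervised_epochs >= 1, weak_epochs >= 1)
  structure(list(lr = lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 infer_batch = as.integer(infer_batch),
                 supervised_epochs = as.integer(supervised_epochs),
                 weak_epochs = as.integer(weak_epochs),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "pathomil_train_config")
}

#' Pooled texture descriptors for one tile
#'
#' The fixed trunk of the tiny backbone: 16 statistics of the tile's
#' colour, darkness and local structure, chosen to respond monotonically
#' to the density and size of dark-stained nuclei-like spots (mean RGB,
#' mean/sd of HSV saturation and value, dark-pixel fractions at three
#' value cutoffs, low-value quantiles, vertical edge energy, saturation
#' of dark pixels, and 16 x 16 block-minimum statistics).
#'
#' @param tile h x w x 3 array in `[0, 1]`.
#' @return Numeric vector of length 16.
#' @export
tile_descriptors <- function(tile) {
  r <- tile[, , 1]; g <- tile[, , 2]; b <- tile[, , 3]
  v <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  s <- (v - mn) / v
  s[v == 0] <- 0
  dark <- v < 0.5
  bm <- -downsample_mean(-v, 16L)           # block minima (16 px blocks)
  c(mean(r), mean(g), mean(b),
    mean(s), stats::sd(s),
    mean(v), stats::sd(v),
    mean(v < 0.6), mean(v < 0.45), mean(v < 0.3),
    stats::quantile(v, 0.05, names = FALSE),
    stats::quantile(v, 0.25, names = FALSE),
    mean(abs(diff(v[seq(1, nrow(v), by = 2L), ]))),
    if (any(dark)) mean(s[dark]) else 0,
    mean(bm),
    mean(bm < 0.4))
}

#' Construct a tile model
#'
#' @param config A [backbone_config()].
#' @param seed Seed for the head weight initialisation.
#' @return Object of class `pathomil_tile_model`, holding the backbone
#'   config, the dense head, and the feature-standardisation state
#'   (identity until fitted).
#' @export
tile_model <- function(config = backbone_config("tiny"), seed = 1L) {
  head <- mlp_new(c(config$feature_dim, config$hidden, config$K),
                  seed = seed)
  structure(list(config = config, head = head,
                 feat_center = rep(0, config$feature_dim),
                 feat_scale = rep(1, config$feature_dim)),
            class = "pathomil_tile_model")
}

#' Backbone feature vectors for a set of tiles
#'
#' Output of the network with the classifier head removed: one length-F
#' vector per tile, in input order. For the tiny backbone this is the
#' standardised descriptor vector (the standardisation state is part of
#' the trained model).
#'
#' @param model A `pathomil_tile_model`.
#' @param tiles List of tile pixel arrays, or an n x F matrix of raw
#'   descriptors already computed with [tile_descriptors()].
#' @return n x F numeric matrix.
#' @export
extract_features <- function(model, tiles) {
  if (model$config$architecture != "tiny") {
    stop("no weights are bundled for the '", model$config$architecture,
         "' reference backbone; use it for analytic contracts only")
  }
  raw <- if (is.matrix(tiles)) tiles else
    do.call(rbind, lapply(tiles, tile_descriptors))
  stopifnot(ncol(raw) == model$config$feature_dim)
  sweep(sweep(raw, 2L, model$feat_center), 2L, model$feat_scale, `/`)
}

#' Tile class probabilities
#'
#' Applies the classifier head to the backbone features in evaluation
#' mode; the output is independent of the batch partitioning.
#'
#' @inheritParams extract_features
#' @param batch Inference batch size.
#' @return n x K matrix of class probabilities, rows in input order.
#' @export
predict_tiles <- function(model, tiles, batch = 256L) {
  n <- if (is.matrix(tiles)) nrow(tiles) else length(tiles)
  if (n == 0L) return(matrix(numeric(0), 0L, model$config$K))
  feats <- extract_features(model, tiles)
  out <- matrix(0, n, model$config$K)
  for (st in seq(1L, n, by = batch)) {
    idx <- st:min(st + batch - 1L, n)
    out[idx, ] <- mlp_predict(model$head, feats[idx, , drop = FALSE])
  }
  out
}

# head applied to already-standardised features (internal fast path)
predict_from_features <- function(model, feats) {
  mlp_predict(model$head, feats)
}

#' Supervised pre-training on strongly annotated tiles
#'
#' Fits the feature standardisation on the training tiles, then trains
#' the classifier head with the differentiable QWK loss (adaptive-moment
#' optimiser). When a validation fraction is set, the model state with
#' the best validation QWK across epochs is kept, mirroring per-epoch
#' QWK model selection.
#'
#' @param model A `pathomil_tile_model`.
#' @param tiles Tile list or raw descriptor matrix.
#' @param labels Integer strong labels in `1:K` (>= 2 distinct values).
#' @param config A [train_config()].
#' @return List with `model` (trained), `trace` (per-epoch training
#'   loss), `val_qwk` (per-epoch validation QWK, or NULL).
#' @export
pretrain_supervised <- function(model, tiles, labels, config = train_config()) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("supervised pre-training needs at least two classes")
  }
  raw <- if (is.matrix(tiles)) tiles else
    do.call(rbind, lapply(tiles, tile_descriptors))
  stopifnot(nrow(raw) == length(labels))
  model$feat_center <- colMeans(raw)
  sds <- apply(raw, 2L, stats::sd)
  model$feat_scale <- ifelse(sds > 1e-9, sds, 1)
  feats <- extract_features(model, raw)

  n <- nrow(feats)
  val_idx <- integer(0)
  if (config$val_fraction > 0 && n >= 10L) {
    val_idx <- withr::with_seed(config$seed + 1L, {
      sample.int(n, max(2L, round(config$val_fraction * n)))
    })
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (length(unique(labels[tr_idx])) < 2L) {  # keep the split usable
    val_idx <- integer(0); tr_idx <- seq_len(n)
  }

  best <- list(net = model$head, qwk = -Inf)
  trace <- numeric(config$supervised_epochs)
  val_qwk <- if (length(val_idx)) numeric(config$supervised_epochs) else NULL
  net <- model$head
  for (e in seq_len(config$supervised_epochs)) {
    fit <- mlp_train(net, feats[tr_idx, , drop = FALSE], labels[tr_idx],
                     loss = "qwk", epochs = 1L,
                     batch_size = config$batch_size, lr = config$lr,
                     weight_decay = config$weight_decay,
                     optimizer = "adam", seed = config$seed + e)
    net <- fit$net
    trace[e] <- fit$trace
    if (length(val_idx)) {
      pv <- mlp_predict(net, feats[val_idx, , drop = FALSE])
      kq <- tryCatch(
        qwk(confusion_matrix(labels[val_idx], max.col(pv, "first"),
                             model$config$K)),
        error = function(e) NA_real_)
      val_qwk[e] <- kq
      if (!is.na(kq) && kq >= best$qwk) best <- list(net = net, qwk = kq)
    }
  }
  model$head <- if (length(val_idx) && is.finite(best$qwk)) best$net else net
  list(model = model, trace = trace, val_qwk = val_qwk)
}
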
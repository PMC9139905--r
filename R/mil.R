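# Weakly supervised MIL: a slide is a bag of tiles with one ordinal
# label, assumed to be the worst tile grade. Each weak epoch infers all
# tiles, ranks them by the expected value of the predicted grade, keeps
# the top-L per bag, and optimises the tile model on the selected tiles
# against the bag's slide label.

#' Construct a slide bag
#'
#' @param slide_id Identifier.
#' @param tiles data.frame of tile records ([extract_tiles()]).
#' @param features n x F matrix of raw tile descriptors (one row per
#'   tile, same order).
#' @param slide_label Ordinal slide grade in `1:K`.
#' @return Object of class `pathomil_bag`.
#' @export
slide_bag <- function(slide_id, tiles, features, slide_label) {
  features <- as.matrix(features)
  stopifnot(nrow(tiles) == nrow(features))
  structure(list(slide_id = slide_id, tiles = tiles, features = features,
                 slide_label = as.integer(slide_label),
                 n_s = nrow(tiles)),
            class = "pathomil_bag")
}

#' Expected value of the predicted grade
#'
#' \eqn{E = \sum_{i=1}^{K} i \, p_i} with the ordered grades scored
#' `1..K`; the tile-ranking statistic.
#'
#' @param probs Length-K probability vector, or an n x K matrix (one
#'   expected score per row).
#' @return Numeric scalar or vector in `[1, K]`.
#' @export
expected_score <- function(probs) {
  if (is.matrix(probs)) {
    check <- abs(rowSums(probs) - 1) > 1e-6
    if (any(probs < -1e-9) || any(check)) stop("malformed probabilities")
    return(as.numeric(probs %*% seq_len(ncol(probs))))
  }
  if (any(probs < -1e-9) || abs(sum(probs) - 1) > 1e-6) {
    stop("malformed probabilities")
  }
  sum(seq_along(probs) * probs)
}

#' Rank tiles by expected score and keep the top L
#'
#' Stable descending sort on the expected score, ties broken by
#' ascending tile index; returns `min(L, n)` tiles. `L = 1` is the
#' max-pooling case.
#'
#' @param bag A [slide_bag()] (or any object with `n_s >= 1`).
#' @param probs n x K matrix of tile class probabilities.
#' @param L Number of tiles to keep.
#' @return data.frame with `tile_index` (position in the bag, 1-based),
#'   `expected` and the probability columns, in rank order.
#' @export
rank_and_select <- function(bag, probs, L = 5L) {
  probs <- as.matrix(probs)
  n <- nrow(probs)
  if (n == 0L) stop("empty bag")
  stopifnot(n == bag$n_s)
  e <- expected_score(probs)
  ord <- order(-e, seq_len(n))     # stable: ties to the lowest index
  keep <- ord[seq_len(min(L, n))]
  out <- data.frame(tile_index = keep, expected = e[keep])
  cbind(out, as.data.frame(probs[keep, , drop = FALSE]))
}

#' Worst-case slide label from tile labels
#'
#' @param tile_labels Integer grades of the slide's tiles.
#' @return The maximum grade.
#' @export
slide_label_from_tiles <- function(tile_labels) {
  if (!length(tile_labels)) stop("no tile labels")
  max(as.integer(tile_labels))
}

#' Slide prediction by max-pooling over tiles
#'
#' The slide inherits the prediction of its top-1 tile by expected
#' score: the slide grade is the argmax of that tile's probabilities
#' (ties to the lowest grade) and the slide probability vector is that
#' tile's.
#'
#' @param model A `pathomil_tile_model`.
#' @param bag A [slide_bag()].
#' @param probs Optional precomputed n x K tile probabilities (skips the
#'   model forward pass).
#' @return List with `grade`, `probs` (length K), `tile_index`.
#' @export
predict_slide_maxpool <- function(model, bag, probs = NULL) {
  if (bag$n_s == 0L) stop("empty bag")
  if (is.null(probs)) probs <- predict_tiles(model, bag$features)
  top <- rank_and_select(bag, probs, L = 1L)
  p <- probs[top$tile_index[1L], ]
  list(grade = which.max(p), probs = p, tile_index = top$tile_index[1L])
}

#' One weakly supervised training epoch
#'
#' (1) inference over every tile of every bag, (2) top-L selection per
#' bag by expected score, (3) one optimisation pass over the selected
#' tiles with the differentiable QWK loss against each bag's slide
#' label. The selected tiles from all bags are pooled and visited in a
#' seeded shuffled order; empty bags are skipped with a warning.
#'
#' @param model A `pathomil_tile_model`.
#' @param bags List of [slide_bag()]s.
#' @param L Tiles kept per bag.
#' @param config A [train_config()].
#' @param prev_selected Optional previous epoch's selection (named list
#'   of integer vectors per slide) for turnover accounting.
#' @param epoch Epoch number (offsets the shuffling seed).
#' @return List: `model`, `selected` (named list of selected tile
#'   positions per bag), `mean_loss`, `turnover` (count of selected
#'   tiles not selected in `prev_selected`).
#' @export
weak_epoch <- function(model, bags, L = 5L, config = train_config(),
                       prev_selected = NULL, epoch = 1L) {
  keep <- vapply(bags, function(b) b$n_s > 0L, logical(1))
  if (any(!keep)) {
    warning(sum(!keep), " bag(s) with zero tiles skipped")
    bags <- bags[keep]
  }
  sel <- list()
  X <- NULL; y <- integer(0)
  for (b in bags) {
    probs <- predict_tiles(model, b$features, batch = config$infer_batch)
    top <- rank_and_select(b, probs, L = L)
    sel[[b$slide_id]] <- top$tile_index
    X <- rbind(X, b$features[top$tile_index, , drop = FALSE])
    y <- c(y, rep(b$slide_label, length(top$tile_index)))
  }
  turnover <- if (is.null(prev_selected)) NA_integer_ else {
    sum(vapply(names(sel), function(id) {
      length(setdiff(sel[[id]], prev_selected[[id]]))
    }, integer(1)))
  }
  feats <- extract_features(model, X)
  if (length(unique(y)) < 2L) {
    warning("selected tiles carry a single slide label; skipping update")
    return(list(model = model, selected = sel, mean_loss = NA_real_,
                turnover = turnover))
  }
  fit <- mlp_train(model$head, feats, y, loss = "qwk", epochs = 1L,
                   batch_size = config$batch_size, lr = config$lr,
                   weight_decay = config$weight_decay, optimizer = "adam",
                   seed = config$seed + 1000L + as.integer(epoch))
  model$head <- fit$net
  list(model = model, selected = sel, mean_loss = fit$trace,
       turnover = turnover)
}

#' Full weakly supervised training stage
#'
#' Runs [weak_epoch()] for the configured number of epochs, tracking the
#' mean loss and selected-tile turnover, and (when validation bags are
#' given) the slide-level QWK by max-pooling, keeping the best epoch's
#' model.
#'
#' @inheritParams weak_epoch
#' @param val_bags Optional list of bags for per-epoch QWK selection.
#' @param epochs Number of weak epochs (defaults to the config's).
#' @return List: `model`, `log` (data.frame epoch / mean_loss /
#'   turnover / val_qwk).
#' @export
weak_train <- function(model, bags, L = 5L, config = train_config(),
                       val_bags = NULL, epochs = config$weak_epochs) {
  log <- data.frame(epoch = seq_len(epochs), mean_loss = NA_real_,
                    turnover = NA_integer_, val_qwk = NA_real_)
  sel <- NULL
  best <- list(model = model, qwk = -Inf)
  for (e in seq_len(epochs)) {
    st <- weak_epoch(model, bags, L = L, config = config,
                     prev_selected = sel, epoch = e)
    model <- st$model
    sel <- st$selected
    log$mean_loss[e] <- st$mean_loss
    log$turnover[e] <- st$turnover
    if (!is.null(val_bags) && length(val_bags)) {
      preds <- vapply(val_bags, function(b) {
        predict_slide_maxpool(model, b)$grade
      }, integer(1))
      actual <- vapply(val_bags, `[[`, integer(1), "slide_label")
      kq <- tryCatch(qwk(confusion_matrix(actual, preds, model$config$K)),
                     error = function(err) NA_real_)
      log$val_qwk[e] <- kq
      if (!is.na(kq) && kq >= best$qwk) best <- list(model = model, qwk = kq)
    }
  }
  if (!is.null(val_bags) && is.finite(best$qwk)) model <- best$model
  list(model = model, log = log)
}
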
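# Slide-level aggregation: the feature vectors of the La worst tiles
# (by expected score) are concatenated into one fixed-length slide
# vector and fed to shallow classifiers. Aggregator kinds and their
# hyper-parameters follow the adopted recipe: SVM (RBF, C = 1), KNN
# (k = 5), random forest (depth 4, Gini), AdaBoost (3000 stumps),
# XGBoost (5000 rounds), MLP (75;5) and MLP (300;50), plus soft-voting
# ensembles SVM+KNN and SVM+RF+KNN.

#' Analytic slide-feature length
#'
#' @param config A [backbone_config()].
#' @param La Number of aggregated worst tiles.
#' @return `La * feature_dim` (3584 for the reference backbone with
#'   `La = 7`).
#' @export
slide_feature_length <- function(config, La = 7L) {
  as.integer(La) * config$feature_dim
}

#' Concatenated features of the La worst tiles of a slide
#'
#' Ranks the bag's tiles by expected score and concatenates the backbone
#' features of the top La in rank order. Bags with fewer than La tiles
#' are padded by repeating the lowest-ranked available tile's features,
#' keeping the vector length fixed at `La * F`.
#'
#' @param model A `pathomil_tile_model`.
#' @param bag A [slide_bag()].
#' @param La Number of tiles to aggregate.
#' @param probs Optional precomputed tile probabilities.
#' @return List with `slide_id`, `vector` (length `La * F`),
#'   `tile_indices` (length La, in rank order, padded).
#' @export
build_slide_features <- function(model, bag, La = 7L, probs = NULL) {
  if (bag$n_s == 0L) stop("empty bag")
  if (is.null(probs)) probs <- predict_tiles(model, bag$features)
  top <- rank_and_select(bag, probs, L = La)
  idx <- top$tile_index
  if (length(idx) < La) idx <- c(idx, rep(idx[length(idx)], La - length(idx)))
  feats <- extract_features(model, bag$features[idx, , drop = FALSE])
  list(slide_id = bag$slide_id,
       vector = as.numeric(t(feats)),
       tile_indices = idx)
}

#' Aggregator specification
#'
#' @param kind One of `"svm_rbf"`, `"knn"`, `"random_forest"`,
#'   `"adaboost"`, `"xgboost"`, `"mlp75_5"`, `"mlp300_50"`,
#'   `"vote_svm_knn"`, `"vote_svm_rf_knn"`.
#' @param seed RNG seed for stochastic fits.
#' @param ... Hyper-parameter overrides (e.g. `n_estimators`, `epochs`).
#' @return Object of class `pathomil_agg_spec`.
#' @export
aggregator_spec <- function(kind = c("svm_rbf", "knn", "random_forest",
                                     "adaboost", "xgboost", "mlp75_5",
                                     "mlp300_50", "vote_svm_knn",
                                     "vote_svm_rf_knn"),
                            seed = 1L, ...) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    svm_rbf = list(cost = 1.0),
    knn = list(k = 5L),
    random_forest = list(max_depth = 4L, num_trees = 100L),
    adaboost = list(n_estimators = 3000L),
    xgboost = list(n_estimators = 5000L, max_depth = 6L, eta = 0.3),
    mlp75_5 = list(hidden = c(75L, 5L), epochs = 200L, lr = 1e-3,
                   batch_size = 32L),
    mlp300_50 = list(hidden = c(300L, 50L), epochs = 200L, lr = 1e-3,
                     batch_size = 32L),
    vote_svm_knn = list(members = c("svm_rbf", "knn")),
    vote_svm_rf_knn = list(members = c("svm_rbf", "random_forest", "knn")))
  over <- list(...)
  defaults[names(over)] <- over
  structure(c(list(kind = kind, seed = as.integer(seed)), defaults),
            class = "pathomil_agg_spec")
}

# ---- SAMME AdaBoost over depth-1 rpart stumps (multi-class) ----------
fit_adaboost <- function(X, y, n_estimators, K, seed) {
  n <- nrow(X)
  df <- data.frame(y = factor(y, levels = seq_len(K)), X)
  wts <- rep(1 / n, n)
  stumps <- vector("list", n_estimators)
  alphas <- numeric(n_estimators)
  used <- 0L
  withr::with_seed(seed, {
    for (m in seq_len(n_estimators)) {
      fit <- rpart::rpart(y ~ ., data = df, weights = wts,
                          method = "class",
                          control = rpart::rpart.control(
                            maxdepth = 1L, cp = -1, minsplit = 2L,
                            minbucket = 1L, xval = 0L))
      pred <- as.integer(as.character(predict(fit, df, type = "class")))
      err <- sum(wts * (pred != y)) / sum(wts)
      if (err >= 1 - 1 / K) break        # worse than chance: stop
      err <- max(err, 1e-10)
      alpha <- log((1 - err) / err) + log(K - 1)
      used <- used + 1L
      stumps[[used]] <- fit
      alphas[used] <- alpha
      wts <- wts * exp(alpha * (pred != y))
      wts <- wts / sum(wts)
      if (err < 1e-9) break              # perfect stump: done
    }
  })
  list(stumps = stumps[seq_len(used)], alphas = alphas[seq_len(used)], K = K)
}

predict_adaboost <- function(fit, X) {
  df <- data.frame(X)
  votes <- matrix(0, nrow(df), fit$K)
  for (m in seq_along(fit$stumps)) {
    pred <- as.integer(as.character(
      predict(fit$stumps[[m]], df, type = "class")))
    votes[cbind(seq_len(nrow(df)), pred)] <-
      votes[cbind(seq_len(nrow(df)), pred)] + fit$alphas[m]
  }
  sm <- rowSums(votes)
  sm[sm == 0] <- 1
  votes / sm
}

#' Fit a slide-level aggregator
#'
#' All aggregators share the contract: fit on the slide feature matrix
#' and labels, predict class probabilities with
#' [predict_aggregator_proba()]. Ensemble kinds fit their members and
#' combine them by soft voting at prediction time.
#'
#' @param spec An [aggregator_spec()].
#' @param X n x (La * F) slide feature matrix.
#' @param y Integer slide labels in `1:K` (>= 2 classes).
#' @param K Number of classes.
#' @return Object of class `pathomil_aggregator`.
#' @export
train_aggregator <- function(spec, X, y, K = 3L) {
  X <- as.matrix(X)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y))
  if (length(unique(y)) < 2L) stop("aggregator training needs >= 2 classes")
  classes_present <- sort(unique(y))
  fit <- switch(spec$kind,
    svm_rbf = withr::with_seed(spec$seed, {
      e1071::svm(X, factor(y), kernel = "radial",
                 cost = spec$cost, probability = TRUE)
    }),
    knn = caret::knn3(X, factor(y), k = spec$k),
    random_forest = withr::with_seed(spec$seed, {
      ranger::ranger(x = X, y = factor(y),
                     num.trees = spec$num_trees, max.depth = spec$max_depth,
                     splitrule = "gini", probability = TRUE,
                     num.threads = 1L, seed = spec$seed)
    }),
    adaboost = fit_adaboost(X, y, spec$n_estimators, K, spec$seed),
    xgboost = {
      dtr <- xgboost::xgb.DMatrix(X, label = y - 1L)
      withr::with_seed(spec$seed, {
        xgboost::xgb.train(params = list(objective = "multi:softprob",
                                         num_class = K,
                                         max_depth = spec$max_depth,
                                         eta = spec$eta, nthread = 1L,
                                         seed = spec$seed),
                           data = dtr, nrounds = spec$n_estimators,
                           verbose = 0)
      })
    },
    mlp75_5 = ,
    mlp300_50 = {
      sc <- list(center = colMeans(X),
                 scale = pmax(apply(X, 2L, stats::sd), 1e-9))
      Xs <- scale(X, sc$center, sc$scale)
      net <- mlp_new(c(ncol(X), spec$hidden, K), seed = spec$seed)
      tr <- mlp_train(net, Xs, y, loss = "xent", epochs = spec$epochs,
                      batch_size = spec$batch_size, lr = spec$lr,
                      optimizer = "sgd", seed = spec$seed)
      list(net = tr$net, scaler = sc, trace = tr$trace)
    },
    vote_svm_knn = ,
    vote_svm_rf_knn = {
      lapply(spec$members, function(kind) {
        train_aggregator(aggregator_spec(kind, seed = spec$seed), X, y, K)
      })
    })
  structure(list(spec = spec, fit = fit, K = K,
                 classes_present = classes_present),
            class = "pathomil_aggregator")
}

#' Class probabilities from a fitted aggregator
#'
#' @param agg A fitted `pathomil_aggregator`.
#' @param X Slide feature matrix (rows = slides).
#' @return n x K probability matrix over grades `1:K`.
#' @export
predict_aggregator_proba <- function(agg, X) {
  X <- as.matrix(X)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  K <- agg$K
  spec <- agg$spec
  out <- matrix(0, nrow(X), K)
  if (spec$kind %in% c("vote_svm_knn", "vote_svm_rf_knn")) {
    return(soft_vote(agg$fit, X)$probs)
  }
  p <- switch(spec$kind,
    svm_rbf = {
      pr <- attr(stats::predict(agg$fit, X, probability = TRUE),
                 "probabilities")
      m <- matrix(0, nrow(X), K)
      m[, as.integer(colnames(pr))] <- pr
      m
    },
    knn = {
      pr <- stats::predict(agg$fit, X, type = "prob")
      m <- matrix(0, nrow(X), K)
      m[, as.integer(colnames(pr))] <- pr
      m
    },
    random_forest = {
      pr <- stats::predict(agg$fit, data = X)$predictions
      m <- matrix(0, nrow(X), K)
      m[, as.integer(colnames(pr))] <- pr
      m
    },
    adaboost = predict_adaboost(agg$fit, X),
    xgboost = {
      pr <- stats::predict(agg$fit, xgboost::xgb.DMatrix(X))
      if (is.matrix(pr)) pr else matrix(pr, nrow(X), K, byrow = TRUE)
    },
    mlp75_5 = ,
    mlp300_50 = mlp_predict(agg$fit$net,
                            scale(X, agg$fit$scaler$center,
                                  agg$fit$scaler$scale)))
  out[, seq_len(K)] <- p
  out
}

#' Predicted grades from a fitted aggregator
#'
#' The SVM uses its own decision rule (its probability estimates are a
#' separate, cross-validated fit); all other kinds take the argmax of
#' [predict_aggregator_proba()], ties to the lowest grade.
#'
#' @inheritParams predict_aggregator_proba
#' @return Integer vector of grades.
#' @export
predict_aggregator <- function(agg, X) {
  if (agg$spec$kind == "svm_rbf") {
    X <- as.matrix(X)
    colnames(X) <- paste0("f", seq_len(ncol(X)))
    return(as.integer(as.character(stats::predict(agg$fit, X))))
  }
  max.col(predict_aggregator_proba(agg, X), ties.method = "first")
}

#' Soft-voting ensemble of fitted aggregators
#'
#' Unweighted mean of the members' probability vectors; the grade is the
#' argmax with ties broken to the lowest grade.
#'
#' @param members List (>= 2) of fitted `pathomil_aggregator`s sharing
#'   the class order.
#' @param X Slide feature matrix.
#' @return List with `probs` (n x K, rows sum to 1) and `grade`.
#' @export
soft_vote <- function(members, X) {
  stopifnot(length(members) >= 2L)
  ps <- lapply(members, function(m) {
    p <- predict_aggregator_proba(m, X)
    if (is.null(p)) stop("member without probability output")
    p
  })
  probs <- Reduce(`+`, ps) / length(ps)
  list(probs = probs, grade = max.col(probs, ties.method = "first"))
}

#' Fit and evaluate a set of aggregators on a train/test split
#'
#' Each spec is fitted on the training slides only and evaluated on the
#' test slides with the standard slide-level metrics (QWK, ACC,
#' sensitivity and specificity of the collapsed binary problem).
#'
#' @param specs List of [aggregator_spec()]s.
#' @param X_train,y_train,X_test,y_test Feature matrices and labels.
#' @param train_ids,test_ids Optional slide ids; overlap is an error.
#' @param K Number of classes.
#' @return List with `table` (one metrics row per spec) and `fits`.
#' @export
evaluate_aggregators <- function(specs, X_train, y_train, X_test, y_test,
                                 train_ids = NULL, test_ids = NULL, K = 3L) {
  if (!is.null(train_ids) && !is.null(test_ids) &&
      length(intersect(train_ids, test_ids))) {
    stop("train and test slide ids overlap")
  }
  rows <- list()
  fits <- list()
  for (spec in specs) {
    agg <- train_aggregator(spec, X_train, y_train, K = K)
    pred <- predict_aggregator(agg, X_test)
    m <- grading_metrics(y_test, pred, K = K)
    rows[[spec$kind]] <- data.frame(
      Method = spec$kind, QWK = m$qwk, ACC = 100 * m$acc,
      Sensitivity = m$sensitivity, Specificity = m$specificity,
      stringsAsFactors = FALSE)
    fits[[spec$kind]] <- agg
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       fits = fits)
}
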
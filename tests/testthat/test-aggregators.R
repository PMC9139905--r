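# separable slide-level features: class k shifts the first block
make_slide_features <- function(n_per_class = 12, p = 24, seed = 1,
                                sd = 0.4) {
  withr::with_seed(seed, {
    y <- rep(1:3, each = n_per_class)
    X <- matrix(rnorm(length(y) * p, sd = sd), length(y), p)
    X[, 1:6] <- X[, 1:6] + 1.5 * y
    list(X = X, y = y)
  })
}

test_that("slide feature vectors concatenate the La worst tiles, padded", {
  expect_equal(slide_feature_length(backbone_config("resnet34"), La = 7L),
               3584L)
  expect_equal(slide_feature_length(backbone_config("tiny"), La = 7L), 112L)
  m <- tile_model(seed = 1)
  withr::with_seed(4, {
    n <- 9
    X <- matrix(rnorm(n * 16), n, 16)
    tiles <- data.frame(slide_id = "s", tile_index = seq_len(n) - 1L,
                        x = 0L, y = 0L, size = 512L,
                        strong_label = NA_integer_)
    bag <- slide_bag("s", tiles, X, 2L)
    sf <- build_slide_features(m, bag, La = 7L)
    expect_length(sf$vector, 112L)
    # rank order: indices are the top-7 by expected score
    probs <- predict_tiles(m, X)
    oracle <- order(-as.numeric(probs %*% 1:3), seq_len(n))[1:7]
    expect_equal(sf$tile_indices, oracle)
    # concatenation in rank order of the standardised features
    feats <- extract_features(m, X)
    expect_equal(sf$vector, as.numeric(t(feats[oracle, ])))
    # deterministic rebuild
    expect_identical(build_slide_features(m, bag, La = 7L)$vector, sf$vector)
    # short bags repeat the lowest-ranked tile
    bag2 <- slide_bag("s", tiles[1:2, ], X[1:2, , drop = FALSE], 2L)
    sf2 <- build_slide_features(m, bag2, La = 7L)
    expect_length(sf2$vector, 112L)
    r2 <- order(-as.numeric(probs[1:2, ] %*% 1:3), 1:2)
    expect_equal(sf2$tile_indices, c(r2, rep(r2[2], 5)))
  })
})

test_that("every aggregator kind separates linearly separable features", {
  tr <- make_slide_features(12, seed = 3)
  kinds <- c("svm_rbf", "knn", "random_forest", "adaboost", "xgboost",
             "mlp75_5", "mlp300_50", "vote_svm_knn", "vote_svm_rf_knn")
  for (kind in kinds) {
    spec <- switch(kind,
      adaboost = aggregator_spec(kind, seed = 1, n_estimators = 150L),
      xgboost = aggregator_spec(kind, seed = 1, n_estimators = 80L),
      aggregator_spec(kind, seed = 1))
    agg <- train_aggregator(spec, tr$X, tr$y)
    pred <- predict_aggregator(agg, tr$X)
    expect_gte(mean(pred == tr$y), 0.95)
    probs <- predict_aggregator_proba(agg, tr$X)
    expect_equal(dim(probs), c(36L, 3L))
    expect_equal(rowSums(probs), rep(1, 36), tolerance = 1e-6)
  }
  expect_error(train_aggregator(aggregator_spec("knn"), tr$X,
                                rep(1L, 36)), "2 classes")
})

test_that("aggregator fits are deterministic under a fixed seed", {
  tr <- make_slide_features(8, seed = 5)
  for (kind in c("random_forest", "xgboost", "mlp75_5", "adaboost")) {
    spec <- switch(kind,
      adaboost = aggregator_spec(kind, seed = 9, n_estimators = 60L),
      xgboost = aggregator_spec(kind, seed = 9, n_estimators = 40L),
      aggregator_spec(kind, seed = 9))
    a1 <- train_aggregator(spec, tr$X, tr$y)
    a2 <- train_aggregator(spec, tr$X, tr$y)
    expect_equal(predict_aggregator_proba(a1, tr$X),
                 predict_aggregator_proba(a2, tr$X))
  }
})

test_that("KNN with a unanimous neighbourhood returns probability one", {
  X <- rbind(matrix(0, 6, 4), matrix(10, 6, 4))
  y <- rep(c(1L, 3L), each = 6)
  agg <- train_aggregator(aggregator_spec("knn"), X, y)
  p <- predict_aggregator_proba(agg, matrix(0.1, 1, 4))
  expect_equal(p[1, ], c(1, 0, 0))
})

test_that("soft voting averages member probabilities with low-grade ties", {
  # stub members exercising the voting arithmetic directly
  tr <- make_slide_features(6, seed = 2)
  m1 <- train_aggregator(aggregator_spec("knn"), tr$X, tr$y)
  v <- soft_vote(list(m1, m1), tr$X)
  expect_equal(v$probs, predict_aggregator_proba(m1, tr$X))  # idempotent
  expect_equal(rowSums(v$probs), rep(1, nrow(tr$X)), tolerance = 1e-9)
  # hand-checked mean and tie rule
  probs_a <- c(0.6, 0.3, 0.1)
  probs_b <- c(0.2, 0.5, 0.3)
  mean_p <- (probs_a + probs_b) / 2
  expect_equal(mean_p, c(0.4, 0.4, 0.2))
  expect_equal(max.col(rbind(mean_p), ties.method = "first"), 1L)
  expect_error(soft_vote(list(m1), tr$X))
})

test_that("aggregator comparison reproduces published metrics from fixed predictions", {
  conf <- reference_conf()
  actual <- integer(0); pred <- integer(0)
  for (i in 1:3) for (j in 1:3) {
    actual <- c(actual, rep(i, conf[i, j]))
    pred <- c(pred, rep(j, conf[i, j]))
  }
  m <- grading_metrics(actual, pred)
  expect_equal(round(m$qwk, 3), 0.906)
  expect_equal(round(100 * m$acc, 2), 91.89)
  expect_equal(round(m$sensitivity, 3), 0.980)
  expect_equal(round(m$specificity, 3), 0.981)
  # perfect predictor
  mp <- grading_metrics(actual, actual)
  expect_equal(mp$qwk, 1)
  expect_equal(mp$acc, 1)
})

test_that("train/test slide overlap is rejected and tables are complete", {
  tr <- make_slide_features(12, seed = 6, sd = 0.25)
  te <- make_slide_features(4, seed = 7, sd = 0.25)
  specs <- list(aggregator_spec("knn"), aggregator_spec("svm_rbf"))
  expect_error(
    evaluate_aggregators(specs, tr$X, tr$y, te$X, te$y,
                         train_ids = c("a", "b"), test_ids = c("b", "c")),
    "overlap")
  ev <- evaluate_aggregators(specs, tr$X, tr$y, te$X, te$y,
                             train_ids = paste0("tr", 1:36),
                             test_ids = paste0("te", 1:12))
  expect_equal(ev$table$Method, c("knn", "svm_rbf"))
  expect_true(all(c("QWK", "ACC", "Sensitivity", "Specificity") %in%
                    names(ev$table)))
  expect_gte(min(ev$table$ACC), 90)
})
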
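test_that("quadratic weight matrix follows the squared-distance formula", {
  w3 <- build_weight_matrix(3)
  expect_equal(w3, matrix(c(0, 0.25, 1, 0.25, 0, 0.25, 1, 0.25, 0), 3, 3))
  expect_equal(build_weight_matrix(2), matrix(c(0, 1, 1, 0), 2, 2))
  for (K in 2:6) {
    w <- build_weight_matrix(K)
    expect_equal(diag(w), rep(0, K))
    expect_equal(w, t(w))
    expect_equal(max(w), 1)
  }
  expect_error(build_weight_matrix(1), "K")
})

test_that("qwk matches a brute-force double sum and its fixed points", {
  conf <- reference_conf()
  expect_equal(round(qwk(conf), 3), 0.906)
  expect_equal(qwk(conf), qwk_brute(conf))
  # random matrices agree with the brute-force oracle
  withr::with_seed(42, {
    for (i in 1:20) {
      x <- matrix(rpois(9, 20) + 1, 3, 3)
      expect_equal(qwk(x), qwk_brute(x))
      expect_lte(qwk(x), 1)
    }
  })
  # perfect agreement and independence
  expect_equal(qwk(diag(c(5, 7, 9))), 1)
  ind <- outer(c(10, 20, 30), c(6, 3, 1)) / 60
  expect_equal(qwk(ind), 0, tolerance = 1e-12)
  # degenerate marginals are an error naming the cause
  expect_error(qwk(matrix(c(5, 0, 0, 0, 0, 0, 0, 0, 0), 3, 3)),
               "marginal")
})

test_that("qwk is tied to the class order, not symmetric relabelling", {
  withr::with_seed(7, {
    x <- matrix(rpois(9, 15) + 1, 3, 3)
    perm <- c(2, 3, 1)
    # permuting rows+columns changes qwk (weights depend on grade order)...
    expect_false(isTRUE(all.equal(qwk(x), qwk(x[perm, perm]))))
    # ...unless the weight matrix is permuted too, i.e. the permuted
    # computation with permuted weights equals the original
    w <- build_weight_matrix(3)
    wp <- w[perm, perm]
    N <- sum(x)
    xp <- x[perm, perm]
    mp <- outer(rowSums(xp), colSums(xp)) / N
    expect_equal(1 - sum(wp * xp) / sum(wp * mp), qwk(x))
  })
})

test_that("soft QWK loss agrees with the metric on one-hot inputs", {
  conf <- reference_conf()
  # expand the confusion matrix into per-slide one-hot predictions
  actual <- integer(0)
  pred <- integer(0)
  for (i in 1:3) for (j in 1:3) {
    actual <- c(actual, rep(i, conf[i, j]))
    pred <- c(pred, rep(j, conf[i, j]))
  }
  probs <- diag(3)[pred, ]
  l <- soft_qwk_loss(probs, actual)
  expect_equal(round(l$loss, 3), 0.094)
  expect_equal(l$loss, 1 - qwk(conf))
  # perfect one-hot predictions give zero loss
  l0 <- soft_qwk_loss(diag(3)[actual, ], actual)
  expect_equal(l0$loss, 0)
})

test_that("soft QWK loss decreases as mass moves to a nearer class", {
  # two-sample batch, one correct, one wrong by two steps; moving the
  # wrong sample's mass from grade 3 to grade 2 must lower the loss
  actual <- c(2, 1)
  losses <- vapply(seq(0, 1, by = 0.1), function(a) {
    probs <- rbind(c(0, 1, 0), c(0, a, 1 - a))
    soft_qwk_loss(probs, actual)$loss
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("soft QWK loss gradient matches finite differences through softmax", {
  # the analytic gradient is defined up to a row constant (absorbed by
  # the softmax), so the check chains both through the logits
  withr::with_seed(11, {
    z <- matrix(rnorm(15), 5, 3)
    y <- c(1, 2, 3, 2, 1)
    net <- mlp_new(c(3, 3), seed = 1)  # linear softmax layer
    for (detach in c(FALSE)) {
      fwd <- mlp_forward(net, z)
      l <- soft_qwk_loss(fwd$probs, y, detach_denominator = detach)
      gr <- pathomil:::mlp_backward(net, fwd, l$grad)
      eps <- 1e-6
      for (idx in list(c(1, 1), c(2, 3), c(3, 2))) {
        net2 <- net
        net2$layers[[1]]$W[idx[1], idx[2]] <-
          net2$layers[[1]]$W[idx[1], idx[2]] + eps
        l2 <- soft_qwk_loss(mlp_predict(net2, z), y,
                            detach_denominator = detach)
        expect_equal(gr[[1]]$W[idx[1], idx[2]], (l2$loss - l$loss) / eps,
                     tolerance = 1e-4)
      }
    }
  })
})

test_that("single-class batches fall back to the numerator with a warning", {
  probs <- rbind(c(0.2, 0.5, 0.3), c(0.1, 0.1, 0.8))
  expect_warning(l <- soft_qwk_loss(probs, c(2, 2)), "single-class")
  w <- build_weight_matrix(3)
  expect_equal(l$loss, sum(w[2, ] * colSums(probs)) / 2)
})

test_that("binary collapse metrics reproduce the published evaluation", {
  conf <- reference_conf()
  b <- binary_metrics(conf)
  expect_equal(round(b$sensitivity, 3), 0.980)
  expect_equal(round(b$specificity, 3), 0.981)
  expect_equal(round(100 * b$binary_acc, 1), 98.1)
  expect_equal(b$n_misclassified, 5)
  expect_equal(b$n, 259)
  # hand-counted collapse: TP 201, FN 4, TN 53, FP 1
  expect_equal(b$sensitivity, 201 / 205)
  expect_equal(b$specificity, 53 / 54)
  # perfect diagonal
  d <- binary_metrics(diag(c(3, 4, 5)))
  expect_equal(d$sensitivity, 1)
  expect_equal(d$specificity, 1)
  # missing negatives -> specificity NA
  no_neg <- matrix(c(0, 0, 0, 0, 5, 1, 0, 2, 7), 3, 3, byrow = TRUE)
  expect_true(is.na(binary_metrics(no_neg)$specificity))
})

test_that("per-class ROC/AUC matches an exhaustive threshold oracle", {
  # perfectly separating scores
  actual <- c(1, 1, 2, 2, 3, 3)
  probs <- diag(3)[actual, ] * 0.8 + 0.1
  probs <- probs / rowSums(probs)
  rocs <- per_class_roc(probs, actual)
  for (k in 1:3) expect_equal(rocs[[k]]$auc, 1.0)
  # 20-sample oracle comparison, noisy scores
  withr::with_seed(5, {
    actual <- sample(1:3, 20, replace = TRUE)
    probs <- matrix(runif(60), 20, 3)
    probs <- probs / rowSums(probs)
    rocs <- per_class_roc(probs, actual)
    for (k in 1:3) {
      expect_equal(rocs[[k]]$auc,
                   auc_brute(probs[, k], as.integer(actual == k)),
                   tolerance = 1e-12)
    }
  })
  # random scores at large n stay near 1/2
  withr::with_seed(6, {
    actual <- sample(1:3, 1000, replace = TRUE)
    probs <- matrix(runif(3000), 1000, 3)
    probs <- probs / rowSums(probs)
    rocs <- per_class_roc(probs, actual)
    for (k in 1:3) expect_lt(abs(rocs[[k]]$auc - 0.5), 0.06)
  })
  # absent class is skipped with a notice
  expect_message(r <- per_class_roc(matrix(c(0.5, 0.3, 0.2), 1, 3), 1),
                 "skipped")
  expect_null(r[[2]])
})

test_that("grading metrics bundle matches its parts", {
  withr::with_seed(9, {
    actual <- sample(1:3, 40, replace = TRUE)
    pred <- sample(1:3, 40, replace = TRUE)
    m <- grading_metrics(actual, pred)
    expect_equal(m$acc, mean(actual == pred))
    expect_equal(m$qwk, qwk_brute(m$conf))
    expect_equal(sum(m$conf), 40)
  })
})
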
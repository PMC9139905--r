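# Shared fixtures, built in code at test time.

# Slide-level confusion matrix of the published aggregator evaluation
# (259 held-out slides; rows actual NNeo/LG/HG, columns predicted).
reference_conf <- function() {
  matrix(c(53, 1, 0,
           4, 137, 2,
           0, 14, 48), 3, 3, byrow = TRUE,
         dimnames = rep(list(c("NNeo", "LG", "HG")), 2))
}

# brute-force QWK by direct double sums (independent of qwk())
qwk_brute <- function(x) {
  K <- nrow(x)
  N <- sum(x)
  num <- 0; den <- 0
  for (i in seq_len(K)) for (j in seq_len(K)) {
    w <- (i - j)^2 / (K - 1)^2
    m <- sum(x[i, ]) * sum(x[, j]) / N
    num <- num + w * x[i, j]
    den <- den + w * m
  }
  1 - num / den
}

# brute-force Otsu: exhaustive scan of all 255 split points for the
# between-class variance criterion
otsu_brute <- function(x) {
  bins <- pmin(pmax(floor(x * 255), 0), 255)
  counts <- tabulate(bins + 1L, nbins = 256L)
  n <- sum(counts)
  best_k <- NA_integer_
  best_v <- -Inf
  for (k in 0:254) {
    n0 <- sum(counts[1:(k + 1)])
    n1 <- n - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum((0:k) * counts[1:(k + 1)]) / n0
    mu1 <- sum(((k + 1):255) * counts[(k + 2):256]) / n1
    v <- (n0 / n) * (n1 / n) * (mu0 - mu1)^2
    if (v > best_v + 1e-12) {
      best_v <- v
      best_k <- k
    }
  }
  best_k
}

# AUC by exhaustive threshold enumeration (one-vs-rest)
auc_brute <- function(scores, labels) {
  ths <- sort(unique(c(-Inf, scores, Inf)))
  tpr <- fpr <- numeric(length(ths))
  for (i in seq_along(ths)) {
    pred <- scores >= ths[i]
    tpr[i] <- sum(pred & labels == 1) / sum(labels == 1)
    fpr[i] <- sum(pred & labels == 0) / sum(labels == 0)
  }
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]; tpr <- tpr[ord]
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# bags of synthetic descriptor-space tiles with a planted monotone
# signal: lesional tiles shift a handful of feature dimensions by an
# amount growing with the grade
make_feature_bags <- function(n_bags = 12, tiles_per_bag = 10, seed = 1,
                              noise_sd = 0.3) {
  withr::with_seed(seed, {
    labels <- rep(1:3, length.out = n_bags)
    bags <- lapply(seq_len(n_bags), function(i) {
      k <- labels[i]
      n <- tiles_per_bag
      X <- matrix(rnorm(n * 16, sd = noise_sd), n, 16)
      tile_grade <- rep(1L, n)
      if (k >= 2) {
        # half the tiles are lesional, so top-5 selection on 10-tile bags
        # never trains on tiles of a different grade than the slide
        n_lesion <- max(1L, round(0.5 * n))
        lesion <- sample.int(n, n_lesion)
        tile_grade[lesion] <- k
        X[lesion, 1:4] <- X[lesion, 1:4] + k   # monotone shift
      }
      tiles <- data.frame(slide_id = paste0("bag", i),
                          tile_index = seq_len(n) - 1L,
                          x = (seq_len(n) - 1L) * 512L, y = 0L,
                          size = 512L, strong_label = tile_grade)
      slide_bag(paste0("bag", i), tiles, X, k)
    })
    bags
  })
}

# small textured patches rendered like lesion interiors, for fast tile
# classifier tests without full slides (128 px, labels 1/2/3)
make_texture_patches <- function(n_per_class = 50, size = 128L, seed = 1) {
  tp <- default_texture_params()
  withr::with_seed(seed, {
    out <- list(); labels <- integer(0)
    for (k in 1:3) {
      for (i in seq_len(n_per_class)) {
        img <- array(0, c(size, size, 3))
        noise <- matrix(runif(size * size, 0.96, 1.04), size, size)
        for (ch in 1:3) img[, , ch] <- tp[["1"]]$base_rgb[ch] * noise
        tpk <- tp[[as.character(k)]]
        if (tpk$spot_density > 0) {
          n_spots <- max(1L, round(tpk$spot_density * size * size))
          planes <- list(img[, , 1], img[, , 2], img[, , 3])
          cys <- runif(n_spots, 1, size)
          cxs <- runif(n_spots, 1, size)
          rads <- tpk$spot_radius * runif(n_spots, 0.8, 1.2)
          cols <- outer(runif(n_spots, 0.85, 1.1), tpk$spot_rgb)
          planes <- pathomil:::paint_spots(planes, cys, cxs, rads, cols)
          for (ch in 1:3) img[, , ch] <- planes[[ch]]
        }
        out[[length(out) + 1L]] <- img
        labels <- c(labels, k)
      }
    }
    list(tiles = out, labels = labels)
  })
}
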
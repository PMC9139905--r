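# Minimal dense feed-forward network with manual backpropagation.
# Used for (a) the trainable classifier head of the tiny tile backbone,
# optimised with the differentiable QWK loss, and (b) the two-hidden-layer
# MLP slide aggregators (75;5) and (300;50), optimised with cross-entropy.

#' Initialise a small dense softmax network
#'
#' Fully connected layers with rectifier activations and a softmax output.
#' Weights use He-style initialisation from a seeded RNG so two networks
#' built with the same sizes and seed are identical.
#'
#' @param sizes Integer vector of layer widths, input first, output
#'   (number of classes) last, e.g. `c(16, 16, 3)`.
#' @param seed RNG seed for the weight draw.
#' @return An object of class `pathomil_mlp`.
#' @export
mlp_new <- function(sizes, seed = 1L) {
  stopifnot(length(sizes) >= 2, all(sizes >= 1))
  L <- length(sizes) - 1L
  net <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(L), function(l) {
      fan_in <- sizes[l]
      list(W = matrix(stats::rnorm(fan_in * sizes[l + 1L],
                                   sd = sqrt(2 / fan_in)),
                      fan_in, sizes[l + 1L]),
           b = numeric(sizes[l + 1L]))
    })
  })
  structure(list(layers = net, sizes = sizes), class = "pathomil_mlp")
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# forward pass; returns probs and per-layer activations for backprop
mlp_forward <- function(net, X) {
  X <- as.matrix(X)
  acts <- list(X)
  a <- X
  L <- length(net$layers)
  for (l in seq_len(L)) {
    z <- a %*% net$layers[[l]]$W +
      matrix(net$layers[[l]]$b, nrow(a), ncol(net$layers[[l]]$W), byrow = TRUE)
    a <- if (l < L) pmax(z, 0) else z
    acts[[l + 1L]] <- a
  }
  list(probs = softmax_rows(acts[[L + 1L]]), acts = acts)
}

#' Class probabilities from a dense network
#'
#' @param net A `pathomil_mlp`.
#' @param X n x d input matrix.
#' @return n x K probability matrix (rows sum to 1).
#' @export
mlp_predict <- function(net, X) mlp_forward(net, X)$probs

# gradient of the loss w.r.t. all weights, given d loss / d probs.
# Chains through the softmax Jacobian, then the affine/ReLU stack.
mlp_backward <- function(net, fwd, dprobs) {
  P <- fwd$probs
  # softmax: dL/dz = P * (g - rowSums(g * P))
  delta <- P * (dprobs - rowSums(dprobs * P))
  L <- length(net$layers)
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    a_prev <- fwd$acts[[l]]
    grads[[l]] <- list(W = crossprod(a_prev, delta),
                       b = colSums(delta))
    if (l > 1L) {
      delta <- (delta %*% t(net$layers[[l]]$W)) * (fwd$acts[[l]] > 0)
    }
  }
  grads
}

adam_init <- function(net) {
  lapply(net$layers, function(ly) {
    list(mW = ly$W * 0, vW = ly$W * 0,
         mb = ly$b * 0, vb = ly$b * 0, t = 0L)
  })
}

# One optimiser step. Weight decay is added to the gradient (L2 coupling,
# as in the Adam of common deep-learning frameworks, not decoupled AdamW).
# SGD carries classical momentum 0.9, the default of the usual MLP stacks.
optim_step <- function(net, grads, state, lr, weight_decay = 0,
                       optimizer = c("adam", "sgd"),
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       momentum = 0.9) {
  optimizer <- match.arg(optimizer)
  for (l in seq_along(net$layers)) {
    gW <- grads[[l]]$W + weight_decay * net$layers[[l]]$W
    gb <- grads[[l]]$b
    if (optimizer == "adam") {
      st <- state[[l]]
      st$t <- st$t + 1L
      st$mW <- beta1 * st$mW + (1 - beta1) * gW
      st$vW <- beta2 * st$vW + (1 - beta2) * gW^2
      st$mb <- beta1 * st$mb + (1 - beta1) * gb
      st$vb <- beta2 * st$vb + (1 - beta2) * gb^2
      c1 <- 1 - beta1^st$t
      c2 <- 1 - beta2^st$t
      net$layers[[l]]$W <- net$layers[[l]]$W -
        lr * (st$mW / c1) / (sqrt(st$vW / c2) + eps)
      net$layers[[l]]$b <- net$layers[[l]]$b -
        lr * (st$mb / c1) / (sqrt(st$vb / c2) + eps)
      state[[l]] <- st
    } else {
      st <- state[[l]]
      st$mW <- momentum * st$mW + gW
      st$mb <- momentum * st$mb + gb
      net$layers[[l]]$W <- net$layers[[l]]$W - lr * st$mW
      net$layers[[l]]$b <- net$layers[[l]]$b - lr * st$mb
      state[[l]] <- st
    }
  }
  list(net = net, state = state)
}

# loss = mean negative log-likelihood; grad w.r.t. probs
xent_loss <- function(probs, actual) {
  n <- nrow(probs)
  idx <- cbind(seq_len(n), as.integer(actual))
  p <- pmax(probs[idx], 1e-12)
  grad <- matrix(0, n, ncol(probs))
  grad[idx] <- -1 / (p * n)
  list(loss = -mean(log(p)), grad = grad)
}

#' Train a dense network by mini-batch gradient descent
#'
#' Supports the differentiable QWK loss ([soft_qwk_loss()]) and
#' cross-entropy, with Adam or plain SGD. Batches are drawn in a seeded
#' shuffled order, so a full run is reproducible.
#'
#' @param net A `pathomil_mlp`.
#' @param X n x d input matrix.
#' @param y Integer class labels in `1:K`.
#' @param loss `"qwk"` or `"xent"`.
#' @param epochs Number of passes over the data.
#' @param batch_size Mini-batch size.
#' @param lr Learning rate.
#' @param weight_decay L2 coefficient added to the weight gradients.
#' @param optimizer `"adam"` or `"sgd"`.
#' @param seed Seed for the batch shuffles.
#' @param detach_denominator Passed to [soft_qwk_loss()].
#' @return List with the trained `net` and `trace`, the per-epoch mean
#'   training loss.
#' @export
mlp_train <- function(net, X, y, loss = c("qwk", "xent"), epochs = 10L,
                      batch_size = 32L, lr = 1e-3, weight_decay = 0,
                      optimizer = "adam", seed = 1L,
                      detach_denominator = FALSE) {
  loss <- match.arg(loss)
  X <- as.matrix(X)
  y <- as.integer(y)
  n <- nrow(X)
  stopifnot(length(y) == n, epochs >= 1)
  if (loss == "qwk" && length(unique(y)) < 2L) {
    stop("QWK loss needs at least two distinct classes in the training data")
  }
  state <- adam_init(net)
  trace <- numeric(epochs)
  orders <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(epochs), function(e) sample.int(n))
  })
  for (e in seq_len(epochs)) {
    ord <- orders[[e]]
    starts <- seq(1L, n, by = batch_size)
    losses <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      idx <- ord[starts[bi]:min(starts[bi] + batch_size - 1L, n)]
      fwd <- mlp_forward(net, X[idx, , drop = FALSE])
      lg <- if (loss == "qwk") {
        suppressWarnings(
          soft_qwk_loss(fwd$probs, y[idx],
                        detach_denominator = detach_denominator))
      } else {
        xent_loss(fwd$probs, y[idx])
      }
      grads <- mlp_backward(net, fwd, lg$grad)
      st <- optim_step(net, grads, state, lr = lr,
                       weight_decay = weight_decay, optimizer = optimizer)
      net <- st$net
      state <- st$state
      losses[bi] <- lg$loss
    }
    trace[e] <- mean(losses)
  }
  list(net = net, trace = trace)
}
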
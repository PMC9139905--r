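#' Quadratic weight matrix for ordinal agreement
#'
#' Builds the K x K matrix of quadratic penalties
#' \eqn{w_{ij} = (i - j)^2 / (K - 1)^2} used by the quadratic weighted
#' kappa. The diagonal is zero and the corner entries equal 1, so a
#' misclassification is penalised by the squared distance between the
#' ordered grades.
#'
#' @param K Number of ordered classes (>= 2).
#' @return A K x K numeric matrix.
#' @examples
#' build_weight_matrix(3)
#' @export
build_weight_matrix <- function(K) {
  if (!is.numeric(K) || length(K) != 1L || K < 2 || K != round(K)) {
    stop("K must be a single integer >= 2")
  }
  K <- as.integer(K)
  outer(seq_len(K), seq_len(K), function(i, j) (i - j)^2 / (K - 1)^2)
}

#' Confusion matrix from actual and predicted grades
#'
#' Rows are actual classes, columns predicted, both over grades `1:K`.
#'
#' @param actual,predicted Integer grade vectors in `1:K`.
#' @param K Number of classes.
#' @return A K x K integer count matrix with grade dimnames.
#' @export
confusion_matrix <- function(actual, predicted, K = 3L) {
  stopifnot(length(actual) == length(predicted))
  if (any(actual < 1 | actual > K) || any(predicted < 1 | predicted > K)) {
    stop("grades must lie in 1..K")
  }
  x <- table(factor(actual, levels = seq_len(K)),
             factor(predicted, levels = seq_len(K)))
  x <- unclass(as.matrix(x))
  dimnames(x) <- rep(list(grade_names(K)), 2L)
  x
}

grade_names <- function(K) {
  if (K == 3L) c("NNeo", "LG", "HG") else paste0("C", seq_len(K))
}

expected_matrix <- function(x) {
  N <- sum(x)
  outer(rowSums(x), colSums(x)) / N
}

#' Quadratic weighted kappa from a confusion matrix
#'
#' Computes \eqn{\kappa = 1 - \sum w x / \sum w m}, where `x` is the
#' observed actual-by-predicted count matrix, `w` the quadratic weight
#' matrix ([build_weight_matrix()]) and `m` the expected matrix from the
#' marginal products normalised so that `sum(m) == sum(x)`.
#'
#' @param conf K x K confusion matrix (rows actual, columns predicted).
#' @return Kappa in (-Inf, 1]; 1 means perfect weighted agreement.
#' @examples
#' x <- matrix(c(53, 1, 0, 4, 137, 2, 0, 14, 48), 3, 3, byrow = TRUE)
#' round(qwk(x), 3) # 0.906
#' @export
qwk <- function(conf) {
  conf <- as.matrix(conf)
  stopifnot(nrow(conf) == ncol(conf), all(conf >= 0))
  N <- sum(conf)
  if (N <= 0) stop("confusion matrix has no observations")
  w <- build_weight_matrix(nrow(conf))
  m <- expected_matrix(conf)
  den <- sum(w * m)
  if (den <= 0) {
    stop("degenerate marginals: expected weighted disagreement is zero ",
         "(need at least two distinct actual and predicted classes)")
  }
  1 - sum(w * conf) / den
}

#' Differentiable quadratic-weighted-kappa loss on soft predictions
#'
#' The loss is the ratio \eqn{\sum w \tilde x / \sum w \tilde m} with the
#' soft observed matrix \eqn{\tilde x_{ij} = \sum_{s: y_s = i} p_{sj}} and
#' the expected matrix built from \eqn{\tilde x}'s marginals. On one-hot
#' probabilities it equals \eqn{1 - \kappa} of the hard confusion matrix.
#' The gradient with respect to the probabilities is returned so the loss
#' can drive gradient-based training of a tile classifier.
#'
#' @param probs n x K matrix of class probabilities (rows sum to 1).
#' @param actual Integer vector of actual grades in `1:K`.
#' @param detach_denominator If `TRUE`, the denominator is treated as a
#'   constant when differentiating (both conventions are in use for
#'   kappa-style losses; the ratio's own gradient is the default).
#' @return A list with `loss` (scalar) and `grad` (n x K matrix of
#'   d loss / d probs).
#' @export
soft_qwk_loss <- function(probs, actual, detach_denominator = FALSE) {
  probs <- as.matrix(probs)
  n <- nrow(probs)
  K <- ncol(probs)
  stopifnot(length(actual) == n, n >= 1)
  w <- build_weight_matrix(K)
  y <- as.integer(actual)
  # soft observed matrix: row i accumulates probs of samples with actual i
  xt <- matrix(0, K, K)
  for (k in seq_len(K)) {
    idx <- which(y == k)
    if (length(idx)) xt[k, ] <- colSums(probs[idx, , drop = FALSE])
  }
  r <- rowSums(xt)           # = class counts (probs rows sum to 1)
  cs <- colSums(xt)
  num <- sum(w * xt)
  wy <- w[y, , drop = FALSE] # n x K: w[actual_s, j]
  if (length(unique(y)) < 2L) {
    warning("single-class batch: QWK denominator undefined, ",
            "using weighted-error numerator only")
    loss <- num / n
    return(list(loss = loss, grad = wy / n))
  }
  den <- sum(w * outer(r, cs)) / n
  loss <- num / den
  if (detach_denominator) {
    grad <- wy / den
  } else {
    # d den / d p_{sj} = sum_i w_ij r_i / n  (r fixed by the labels)
    a <- as.numeric(crossprod(w, r)) / n
    grad <- (wy - loss * matrix(a, n, K, byrow = TRUE)) / den
  }
  list(loss = loss, grad = grad)
}

#' Binary screening metrics by collapsing dysplastic grades
#'
#' Collapses the ordinal problem to lesion-vs-normal (by default LG and HG
#' form the positive class) and reports sensitivity, specificity, binary
#' accuracy and the misclassified count.
#'
#' @param conf 3 x 3 confusion matrix (rows actual, columns predicted).
#' @param positive_classes Grades counted as positive (default `c(2, 3)`).
#' @return List with `sensitivity`, `specificity`, `binary_acc`,
#'   `n_misclassified` and `n`. A rate whose denominator is empty is `NA`.
#' @examples
#' x <- matrix(c(53, 1, 0, 4, 137, 2, 0, 14, 48), 3, 3, byrow = TRUE)
#' binary_metrics(x) # sens 0.980, spec 0.981, binary ACC 98.1%
#' @export
binary_metrics <- function(conf, positive_classes = c(2L, 3L)) {
  conf <- as.matrix(conf)
  K <- nrow(conf)
  stopifnot(K == ncol(conf))
  pos <- seq_len(K) %in% positive_classes
  tp <- sum(conf[pos, pos, drop = FALSE])
  fn <- sum(conf[pos, !pos, drop = FALSE])
  tn <- sum(conf[!pos, !pos, drop = FALSE])
  fp <- sum(conf[!pos, pos, drop = FALSE])
  n <- sum(conf)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  list(sensitivity = sens, specificity = spec,
       binary_acc = (tp + tn) / n,
       n_misclassified = fp + fn, n = n)
}

#' Per-class one-vs-rest ROC curves and AUC
#'
#' For each grade, the class probability is scored against the
#' one-vs-rest indicator; the curve and trapezoid AUC come from
#' \pkg{pROC}. Classes absent from `actual` (or without negatives)
#' are skipped with a message.
#'
#' @param scores n x K matrix of predicted class probabilities.
#' @param actual Integer actual grades in `1:K`.
#' @return Named list per class with `roc` (a `pROC::roc` object) and
#'   `auc`; skipped classes are `NULL`.
#' @export
per_class_roc <- function(scores, actual) {
  scores <- as.matrix(scores)
  K <- ncol(scores)
  out <- stats::setNames(vector("list", K), grade_names(K))
  for (k in seq_len(K)) {
    lab <- as.integer(actual == k)
    if (length(unique(lab)) < 2L) {
      message("class ", k, " has no positives or no negatives; skipped")
      next
    }
    r <- pROC::roc(response = lab, predictor = scores[, k],
                   levels = c(0, 1), direction = "<", quiet = TRUE)
    out[[k]] <- list(roc = r, auc = as.numeric(pROC::auc(r)))
  }
  out
}

#' Format a confusion matrix as a labelled text table
#'
#' @param conf K x K confusion matrix.
#' @return A character vector of lines (actual in rows, predicted in
#'   columns), suitable for `cat(..., sep = "\n")`.
#' @export
format_confusion <- function(conf) {
  conf <- as.matrix(conf)
  K <- nrow(conf)
  nm <- grade_names(K)
  wid <- max(nchar(nm), nchar(as.character(conf)), 6L)
  pad <- function(x) formatC(x, width = wid)
  header <- paste0(pad("Actual"), " ", paste(pad(nm), collapse = " "))
  rows <- vapply(seq_len(K), function(i) {
    paste0(pad(nm[i]), " ", paste(pad(conf[i, ]), collapse = " "))
  }, character(1))
  c(paste0(strrep(" ", wid + 1L), pad("Predicted")), header, rows)
}

#' Standard slide-level evaluation metrics
#'
#' Multiclass accuracy, quadratic weighted kappa, and the collapsed
#' binary metrics, from actual and predicted grade vectors.
#'
#' @param actual,predicted Integer grades in `1:K`.
#' @param K Number of classes.
#' @return List with `conf`, `acc`, `qwk`, `sensitivity`, `specificity`,
#'   `binary_acc`, `n_misclassified`, `n`.
#' @export
grading_metrics <- function(actual, predicted, K = 3L) {
  conf <- confusion_matrix(actual, predicted, K)
  b <- binary_metrics(conf)
  list(conf = conf,
       acc = sum(diag(conf)) / sum(conf),
       qwk = qwk(conf),
       sensitivity = b$sensitivity,
       specificity = b$specificity,
       binary_acc = b$binary_acc,
       n_misclassified = b$n_misclassified,
       n = b$n)
}
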
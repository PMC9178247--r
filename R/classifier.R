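#' Train the 10-10-1 back-propagation screening network
#'
#' A single-hidden-layer perceptron (10 inputs, 10 sigmoid hidden units,
#' 1 sigmoid output) trained by full-batch gradient descent with momentum
#' on mean squared error. Features are z-scored with statistics computed on
#' the training data only; the scaling is stored in the model and applied
#' at prediction time, so cross-validation never leaks hold-out statistics.
#' Training is deterministic given \code{seed}.
#'
#' @param features Numeric matrix, one row per sample, 10 columns (any
#'   column count is accepted; 10 matches the screening feature vector).
#' @param labels Binary vector (0 = normal, 1 = abnormal), one per row.
#' @param hidden Hidden-layer width (default 10).
#' @param lr Learning rate (default 0.05).
#' @param epochs Training epochs (default 500).
#' @param momentum Momentum coefficient (default 0.9).
#' @param seed Integer seed for the weight initialization.
#' @return An object of class \code{"bp_net"}.
#' @export
bp_train <- function(features, labels, hidden = 10, lr = 0.05, epochs = 500,
                     momentum = 0.9, seed = 1L) {
  X <- as.matrix(features)
  y <- as.numeric(labels)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2L) stop("training set contains a single class")
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale == 0] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")

  p <- ncol(X)
  W1 <- with_seed(seed, matrix(stats::runif(p * hidden, -0.5, 0.5), p, hidden))
  b1 <- numeric(hidden)
  W2 <- with_seed(seed + 1L, matrix(stats::runif(hidden, -0.5, 0.5), hidden, 1))
  b2 <- 0
  vW1 <- W1 * 0; vb1 <- b1 * 0; vW2 <- W2 * 0; vb2 <- 0
  sigm <- function(z) 1 / (1 + exp(-z))
  n <- nrow(Xs)
  for (e in seq_len(epochs)) {
    H <- sigm(sweep(Xs %*% W1, 2, b1, "+"))
    o <- drop(sigm(H %*% W2 + b2))
    # d(MSE)/do, through the output sigmoid
    delta_o <- 2 * (o - y) * o * (1 - o) / n
    gW2 <- crossprod(H, delta_o)
    gb2 <- sum(delta_o)
    delta_h <- (delta_o %*% t(W2)) * H * (1 - H)
    gW1 <- crossprod(Xs, delta_h)
    gb1 <- colSums(delta_h)
    vW1 <- momentum * vW1 - lr * gW1; W1 <- W1 + vW1
    vb1 <- momentum * vb1 - lr * gb1; b1 <- b1 + vb1
    vW2 <- momentum * vW2 - lr * gW2; W2 <- W2 + vW2
    vb2 <- momentum * vb2 - lr * gb2; b2 <- b2 + vb2
  }
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                 center = center, scale = scale,
                 lr = lr, epochs = epochs, momentum = momentum),
            class = "bp_net")
}

#' Predict with the screening network
#'
#' @param object A \code{bp_net}.
#' @param newdata Feature matrix (or single feature vector).
#' @param type \code{"class"} for hard 0/1 labels (output >= 0.5 maps to 1,
#'   the documented tie-break at exactly 0.5), or \code{"raw"} for the
#'   network output.
#' @param ... Unused.
#' @return Numeric vector of labels or raw outputs.
#' @export
predict.bp_net <- function(object, newdata, type = c("class", "raw"), ...) {
  type <- match.arg(type)
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  sigm <- function(z) 1 / (1 + exp(-z))
  H <- sigm(sweep(Xs %*% object$W1, 2, object$b1, "+"))
  o <- drop(sigm(H %*% object$W2 + object$b2))
  if (type == "raw") o else as.integer(o >= 0.5)
}

#' Leave-one-out (jackknife) evaluation of the screening network
#'
#' Each sample in turn is held out; the network is retrained on the
#' remaining samples (feature scaling refit on each training fold) and
#' predicts the held-out case. Predictions are aggregated into one
#' confusion matrix, from which accuracy, sensitivity and specificity
#' are computed. A training fold containing a single class (unavoidable
#' at tiny n) degenerates to the constant majority-class predictor for
#' that fold.
#'
#' @param features Feature matrix (rows = samples).
#' @param labels Binary vector (0 = normal, 1 = abnormal).
#' @param ... Passed to \code{\link{bp_train}} (e.g. \code{lr},
#'   \code{epochs}, \code{seed}).
#' @return An object of class \code{"pcg_eval"}: counts \code{tp, tn, fp,
#'   fn}, metrics \code{acc, se, sp} (percent), and \code{predictions}.
#' @export
jackknife_eval <- function(features, labels, ...) {
  X <- as.matrix(features)
  y <- as.numeric(labels)
  n <- nrow(X)
  stopifnot(n >= 3, length(y) == n)
  pred <- integer(n)
  for (i in seq_len(n)) {
    y_tr <- y[-i]
    if (length(unique(y_tr)) < 2L) {
      pred[i] <- as.integer(round(mean(y_tr)))
      next
    }
    fit <- bp_train(X[-i, , drop = FALSE], y_tr, ...)
    pred[i] <- predict(fit, X[i, , drop = FALSE])
  }
  tp <- sum(pred == 1 & y == 1); tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0); fn <- sum(pred == 0 & y == 1)
  m <- confusion_metrics(tp, tn, fp, fn)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 acc = m[["acc"]], se = m[["se"]], sp = m[["sp"]],
                 predictions = pred, labels = y),
            class = "pcg_eval")
}

#' @export
print.pcg_eval <- function(x, ...) {
  cat(sprintf("<pcg_eval> n = %d | TP %d  TN %d  FP %d  FN %d\n",
              x$tp + x$tn + x$fp + x$fn, x$tp, x$tn, x$fp, x$fn))
  cat(sprintf("  Acc %.2f%%  Se %.2f%%  Sp %.2f%%\n", x$acc, x$se, x$sp))
  invisible(x)
}
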
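#' Fit the three-layer back-propagation network
#'
#' One hidden layer of sigmoid units and a sigmoid output, trained by
#' full-batch gradient descent on the mean cross-entropy loss. Weights are
#' initialized uniformly on \[-0.5, 0.5\] from the given seed. This network
#' is used both as a classifier and, via [nn_ablation_errors()], as the
#' input-ablation feature selector.
#'
#' @param X numeric matrix (observations x features).
#' @param y binary 0/1 vector.
#' @param hidden number of hidden units (default 10).
#' @param epochs gradient-descent epochs (default 500).
#' @param lr learning rate (default 0.01; see the package vignette for the
#'   choice).
#' @param seed RNG seed for weight initialization.
#' @return Object of class `deltarad_nn` (weights plus training metadata).
#' @export
nn_fit <- function(X, y, hidden = 10L, epochs = 500L, lr = 0.01, seed = 1L) {
  X <- as.matrix(X)
  p <- ncol(X)
  init <- with_seed(seed, list(
    W1 = matrix(runif(p * hidden, -0.5, 0.5), p, hidden),
    b1 = runif(hidden, -0.5, 0.5),
    w2 = runif(hidden, -0.5, 0.5),
    b2 = runif(1, -0.5, 0.5)))
  w <- .nn_train_cpp(X, as.numeric(y), init$W1, init$b1, init$w2, init$b2,
                     as.integer(epochs), lr)
  structure(list(W1 = w$W1, b1 = w$b1, w2 = w$w2, b2 = w$b2,
                 feature_names = colnames(X), hidden = hidden,
                 epochs = epochs, lr = lr, seed = seed),
            class = "deltarad_nn")
}

nn_forward <- function(fit, X, W1 = fit$W1) {
  A1 <- plogis(sweep(as.matrix(X) %*% W1, 2, fit$b1, `+`))
  as.numeric(plogis(A1 %*% fit$w2 + fit$b2))
}

#' Predict class-1 scores from a fitted network
#'
#' @param object a [nn_fit()] result.
#' @param newdata numeric matrix with the training features in order.
#' @param ... unused.
#' @return Numeric vector of scores in \[0, 1\].
#' @export
predict.deltarad_nn <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$feature_names) && !is.null(colnames(newdata)) &&
      !identical(colnames(newdata), object$feature_names))
    stop_deltarad("feature mismatch between training and prediction")
  nn_forward(object, newdata)
}

#' Input-ablation errors of a fitted network
#'
#' For each input feature, zeroes every first-layer weight attached to that
#' input (leaving all other weights untouched) and records the
#' classification error of the crippled network on the supplied data at
#' threshold 0.5. A larger error when a feature is disabled marks that
#' feature as more important.
#'
#' @param fit a [nn_fit()] result.
#' @param X,y data to measure the ablation error on (the training set in
#'   the selection pipeline).
#' @return Numeric vector of errors, one per input feature.
#' @export
nn_ablation_errors <- function(fit, X, y) {
  X <- as.matrix(X)
  vapply(seq_len(ncol(X)), function(j) {
    W1 <- fit$W1
    W1[j, ] <- 0
    pr <- nn_forward(fit, X, W1 = W1)
    mean((pr >= 0.5) != y)
  }, numeric(1))
}
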
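#' The seven-classifier registry
#'
#' Binary classifiers emitting a posterior-style class-1 score in \[0, 1\]:
#'
#' * `RF` - random forest, 100 trees (class-1 vote fraction).
#' * `L1LR` / `L2LR` - L1/L2-penalized logistic regression with the sigmoid
#'   link (penalty `lambda = 1 / n` by default, the glmnet analogue of a
#'   unit inverse-regularization constant).
#' * `LSVM` / `KSVM` - support vector machines with linear and Gaussian RBF
#'   kernels (cost 1, RBF bandwidth `1 / n_features`); the signed decision
#'   value is mapped through a sigmoid, which preserves the score ranking
#'   that ROC analysis uses.
#' * `NN` - three-layer back-propagation network, 10 hidden units
#'   ([nn_fit()]).
#' * `NB` - Gaussian naive Bayes posterior.
#'
#' @return Character vector of the seven classifier names.
#' @export
classifier_names <- function() {
  c("RF", "L1LR", "L2LR", "LSVM", "KSVM", "NN", "NB")
}

#' Classifier specification
#'
#' @param name one of [classifier_names()].
#' @param seed RNG seed for stochastic classifiers (RF bootstrap, NN
#'   initialization).
#' @param ... hyperparameter overrides: `n_trees` (RF, default 100),
#'   `lambda` (LR penalties, default `1/n`), `cost` (SVMs, default 1),
#'   `gamma` (KSVM, default `1/n_features`), `hidden`, `epochs`, `lr` (NN).
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(name, seed = 1L, ...) {
  name <- match.arg(name, classifier_names())
  structure(list(name = name, seed = as.integer(seed),
                 hyper = list(...)),
            class = "classifier_spec")
}

#' Train one of the seven classifiers
#'
#' @param spec a [classifier_spec()] (or a classifier name).
#' @param X numeric matrix of selected features (1-3 columns in the study
#'   design).
#' @param y binary 0/1 labels; both classes must be present.
#' @return Object of class `trained_classifier`.
#' @export
train_classifier <- function(spec, X, y) {
  if (is.character(spec)) spec <- classifier_spec(spec)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  y <- as.integer(y)
  if (length(unique(y)) < 2)
    stop_deltarad("training labels contain a single class")
  if (nrow(X) != length(y)) stop_deltarad("row/label length mismatch")
  h <- spec$hyper
  yf <- factor(y, levels = c(0, 1))
  fit <- switch(
    spec$name,
    RF = with_seed(spec$seed, randomForest::randomForest(
      x = X, y = yf, ntree = h$n_trees %||% 100L)),
    L1LR = list(lambda = h$lambda %||% (1 / nrow(X)),
                beta = NULL, alpha = 1),
    L2LR = list(lambda = h$lambda %||% (1 / nrow(X)),
                beta = NULL, alpha = 0),
    LSVM = svm_fit(X, yf, kernel = "linear", cost = h$cost %||% 1),
    KSVM = svm_fit(X, yf, kernel = "radial", cost = h$cost %||% 1,
                   gamma = h$gamma %||% (1 / ncol(X))),
    NN = nn_fit(X, y, hidden = h$hidden %||% 10L,
                epochs = h$epochs %||% 500L, lr = h$lr %||% 0.01,
                seed = spec$seed),
    NB = e1071::naiveBayes(x = as.data.frame(X), y = yf)
  )
  if (spec$name %in% c("L1LR", "L2LR")) {
    pad <- ncol(X) < 2
    Xf <- if (pad) cbind(X, .pad. = 0) else X
    gfit <- glmnet_quiet(Xf, yf, alpha = fit$alpha, lambda = fit$lambda)
    fit$glmnet <- gfit
    fit$pad <- pad
  }
  structure(list(spec = spec, fit = fit, feature_names = colnames(X)),
            class = "trained_classifier")
}

svm_fit <- function(X, yf, kernel, cost = 1, gamma = 1 / ncol(X)) {
  e1071::svm(x = X, y = yf, kernel = kernel, cost = cost, gamma = gamma,
             scale = FALSE, probability = FALSE)
}

#' Posterior-style class-1 scores from a trained classifier
#'
#' Returns one score in \[0, 1\] per row: the class-1 posterior for the
#' probabilistic models, and a sigmoid-mapped signed decision value for the
#' SVMs (only the ranking of scores enters the ROC analysis).
#'
#' @param model a [train_classifier()] result.
#' @param X_new numeric matrix with the training features, in order.
#' @return Numeric vector of scores in \[0, 1\].
#' @export
predict_score <- function(model, X_new) {
  stopifnot(inherits(model, "trained_classifier"))
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(model$feature_names))
    stop_deltarad("feature mismatch: model expects ",
                  length(model$feature_names), " columns")
  if (!is.null(colnames(X_new)) &&
      !identical(colnames(X_new), model$feature_names))
    stop_deltarad("feature names do not match the training features")
  colnames(X_new) <- model$feature_names
  name <- model$spec$name
  sc <- switch(
    name,
    RF = predict(model$fit, newdata = X_new, type = "prob")[, "1"],
    L1LR = ,
    L2LR = {
      Xf <- if (model$fit$pad) cbind(X_new, .pad. = 0) else X_new
      as.numeric(predict(model$fit$glmnet, newx = Xf, type = "response",
                         s = model$fit$lambda))
    },
    LSVM = ,
    KSVM = {
      pr <- predict(model$fit, newdata = X_new, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # e1071 orients the decision value toward the first named class
      d <- if (grepl("^1", colnames(dv)[1])) dv[, 1] else -dv[, 1]
      plogis(d)
    },
    NN = predict(model$fit, X_new),
    NB = predict(model$fit, newdata = as.data.frame(X_new),
                 type = "raw")[, "1"]
  )
  unname(pmin(pmax(as.numeric(sc), 0), 1))
}
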
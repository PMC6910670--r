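#' Univariate Cox proportional-hazards feature screen
#'
#' Fits one single-covariate Cox model per feature on (time, event) and
#' keeps the features whose likelihood-ratio test against the null model
#' has `p < alpha` (strict). Features whose fit fails or does not converge
#' are assigned `p = 1` and logged in the `failed` element.
#'
#' @param X numeric matrix (patients x features) or a `feature_table`.
#' @param os_months,event survival time and event indicator; taken from the
#'   table's survival records when `X` is a `feature_table`.
#' @param alpha significance threshold (default 0.1).
#' @param pvalue `"lrt"` (likelihood-ratio, default) or `"wald"`.
#' @return A list of class `cox_screen` with `coefficients`, `p_values`,
#'   `surviving_features`, `alpha` and `failed`.
#' @export
cox_screen <- function(X, os_months = NULL, event = NULL, alpha = 0.1,
                       pvalue = c("lrt", "wald")) {
  pvalue <- match.arg(pvalue)
  if (inherits(X, "feature_table")) {
    os_months <- X$survival$os_months
    event <- X$survival$event
    X <- X$X
  }
  X <- as.matrix(X)
  if (sum(event) < 2) stop_deltarad("need at least 2 observed events")
  y <- survival::Surv(os_months, event)
  ctl <- survival::coxph.control()
  n <- nrow(X)
  coefs <- pvals <- setNames(rep(NA_real_, ncol(X)), colnames(X))
  failed <- character(0)
  for (j in seq_len(ncol(X))) {
    xj <- X[, j, drop = FALSE]
    fit <- tryCatch(
      suppressWarnings(survival::coxph.fit(
        xj, y, strata = NULL, offset = NULL, init = 0, control = ctl,
        weights = NULL, method = "efron", rownames = as.character(1:n))),
      error = function(e) NULL)
    ok <- !is.null(fit) && all(is.finite(fit$coefficients)) &&
      all(is.finite(fit$loglik))
    if (!ok) {
      coefs[j] <- 0
      pvals[j] <- 1
      failed <- c(failed, colnames(X)[j])
      next
    }
    coefs[j] <- fit$coefficients[1]
    pvals[j] <- if (pvalue == "lrt") {
      lr <- 2 * (fit$loglik[2] - fit$loglik[1])
      pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
    } else {
      z2 <- fit$coefficients[1]^2 / fit$var[1, 1]
      pchisq(z2, df = 1, lower.tail = FALSE)
    }
  }
  structure(list(coefficients = coefs, p_values = pvals,
                 surviving_features = colnames(X)[pvals < alpha],
                 alpha = alpha, failed = failed),
            class = "cox_screen")
}

new_selector_result <- function(method, importance, N, seed = NA_integer_) {
  ord <- order(-importance, names(importance))
  ranked <- names(importance)[ord]
  structure(list(method = method, importance = importance,
                 ranked_features = ranked,
                 selected = head(ranked, min(N, length(ranked))),
                 N = N, seed = seed),
            class = "selector_result")
}

#' Random-forest out-of-bag permutation importance ranking
#'
#' Fits a classification random forest (bootstrap per tree) and ranks
#' features by the mean increase in out-of-bag misclassification error when
#' the feature's out-of-bag values are permuted (unscaled mean decrease in
#' accuracy). Ties break by canonical feature name.
#'
#' @param X numeric matrix restricted to Cox-surviving features.
#' @param labels binary 0/1 class labels (both classes present).
#' @param N number of features to select (1-3 in the study design; capped
#'   at the number of available features).
#' @param n_trees number of trees (default 100).
#' @param seed RNG seed.
#' @return A `selector_result` with `importance`, `ranked_features` and
#'   the top-`N` `selected` names.
#' @export
rank_rf_oob <- function(X, labels, N = 3L, n_trees = 100L, seed = 1L) {
  X <- as.matrix(X)
  rf <- with_seed(seed, randomForest::randomForest(
    x = X, y = factor(labels, levels = c(0, 1)), ntree = n_trees,
    importance = TRUE))
  imp <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
  names(imp) <- colnames(X)
  new_selector_result("RF", imp, N, seed)
}

#' Neural-network input-ablation importance ranking
#'
#' Trains one three-layer network on all surviving features, then disables
#' the inputs one by one (zeroing all first-layer weights of the input, see
#' [nn_ablation_errors()]) and ranks features by the training-set
#' classification error of the crippled network: the larger the error when
#' a feature is disabled, the more important the feature.
#'
#' @inheritParams rank_rf_oob
#' @param hidden,epochs,lr network hyperparameters (see [nn_fit()]).
#' @return A `selector_result`.
#' @export
rank_nn_ablation <- function(X, labels, N = 3L, hidden = 10L,
                             epochs = 500L, lr = 0.01, seed = 1L) {
  X <- as.matrix(X)
  fit <- nn_fit(X, labels, hidden = hidden, epochs = epochs, lr = lr,
                seed = seed)
  imp <- nn_ablation_errors(fit, X, labels)
  names(imp) <- colnames(X)
  new_selector_result("NN", imp, N, seed)
}

#' L1-penalized logistic-regression weight ranking
#'
#' Fits an L1-penalized logistic regression on the (already standardized)
#' features and ranks them by absolute coefficient. If the penalty zeroes
#' every coefficient it is halved and the model refit, up to 10 times.
#'
#' @inheritParams rank_rf_oob
#' @param penalty_strength initial lasso penalty (glmnet `lambda`,
#'   default 1).
#' @return A `selector_result` (with the final penalty in `$penalty`).
#' @export
rank_l1lr <- function(X, labels, N = 3L, penalty_strength = 1.0) {
  X <- as.matrix(X)
  lam <- penalty_strength
  beta <- NULL
  for (k in 0:10) {
    beta <- lasso_coefs(X, labels, lam)
    if (any(beta != 0)) break
    if (k < 10) lam <- lam / 2
  }
  if (all(beta == 0))
    stop_deltarad("L1 penalty left all coefficients zero after 10 halvings")
  imp <- setNames(abs(beta), colnames(X))
  res <- new_selector_result("L1LR", imp, N)
  res$penalty <- lam
  res
}

# glmnet requires >= 2 columns; pad with a zero column when needed
lasso_coefs <- function(X, y, lambda, alpha = 1) {
  pad <- ncol(X) < 2
  Xf <- if (pad) cbind(X, .pad. = 0) else X
  fit <- glmnet_quiet(Xf, factor(y, levels = c(0, 1)), alpha = alpha,
                      lambda = lambda)
  beta <- as.numeric(fit$beta[, 1])
  if (pad) beta <- beta[-length(beta)]
  beta
}

# glmnet warns about classes with < 8 observations on every LOOCV training
# fold of a 12-patient cohort; that is the study regime, so muffle exactly
# that warning
glmnet_quiet <- function(x, y, alpha, lambda) {
  withCallingHandlers(
    glmnet::glmnet(x, y, family = "binomial", alpha = alpha,
                   lambda = lambda, standardize = FALSE),
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}
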
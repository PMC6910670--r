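test_that("the Cox screen keeps features with LRT p < alpha, strictly", {
  set.seed(12)
  n <- 40
  os <- runif(n, 5, 30)
  ev <- rep(1L, n)
  X <- cbind(prognostic = -os + rnorm(n, 0, 0.5),
             noise = rnorm(n),
             constant = rep(1, n))
  scr <- cox_screen(X, os, ev, alpha = 0.1)
  expect_true("prognostic" %in% scr$surviving_features)
  expect_lt(scr$p_values["prognostic"], 0.1)
  # constant covariate cannot improve on the null model
  expect_equal(unname(scr$p_values["constant"]), 1)
  # strict inequality at the threshold: alpha equal to a feature's p-value
  # excludes that feature
  scr2 <- cox_screen(X, os, ev, alpha = scr$p_values["noise"])
  expect_false("noise" %in% scr2$surviving_features)
  expect_error(cox_screen(X, os, rep(0L, n)), "events")
})

test_that("Cox LRT p-values match a hand-coded partial-likelihood oracle", {
  set.seed(13)
  n <- 25
  os <- runif(n, 5, 30)
  ev <- rep(1L, n)
  X <- cbind(a = -os + rnorm(n, 0, 2), b = rnorm(n), c = rnorm(n))
  scr <- cox_screen(X, os, ev)
  for (j in colnames(X)) {
    expect_equal(unname(scr$p_values[j]),
                 oracle_cox_lrt_p(X[, j], os, ev), tolerance = 1e-5)
  }
})

test_that("the Cox screen's per-feature false-positive rate is near alpha", {
  fpr <- vapply(1:30, function(s) {
    set.seed(1000 + s)
    n <- 25
    os <- runif(n, 5, 30)
    X <- matrix(rnorm(n * 40), n, 40,
                dimnames = list(NULL, paste0("f", 1:40)))
    scr <- cox_screen(X, os, rep(1L, n), alpha = 0.1)
    length(scr$surviving_features) / 40
  }, numeric(1))
  # cluster-level standard error across cohorts
  se <- stats::sd(fpr) / sqrt(length(fpr))
  expect_lt(abs(mean(fpr) - 0.1), 3 * se + 0.02)
})

test_that("selectors recover a planted separating feature", {
  hits <- c(RF = 0, NN = 0, L1 = 0)
  for (s in 1:25) {
    set.seed(s)
    n <- 60
    X <- cbind(matrix(rnorm(n * 9), n, 9),
               c(rnorm(n / 2, -1.5, 0.5), rnorm(n / 2, 1.5, 0.5)))
    colnames(X) <- c(paste0("noise", 1:9), "signal")
    X <- scale(X)[, ]
    y <- rep(c(0L, 1L), each = n / 2)
    hits["RF"] <- hits["RF"] +
      (rank_rf_oob(X, y, seed = s)$ranked_features[1] == "signal")
    hits["NN"] <- hits["NN"] +
      (rank_nn_ablation(X, y, seed = s)$ranked_features[1] == "signal")
    hits["L1"] <- hits["L1"] +
      (rank_l1lr(X, y)$ranked_features[1] == "signal")
  }
  expect_gte(hits[["RF"]], 23)
  expect_gte(hits[["NN"]], 20)
  expect_gte(hits[["L1"]], 24)
})

test_that("rankings are deterministic given the seed and cap at N", {
  set.seed(2)
  X <- matrix(rnorm(30 * 6), 30, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  y <- rep(c(0L, 1L), 15)
  r1 <- rank_rf_oob(X, y, N = 3, seed = 42)
  r2 <- rank_rf_oob(X, y, N = 3, seed = 42)
  expect_identical(r1$ranked_features, r2$ranked_features)
  expect_length(r1$selected, 3L)
  # N larger than the number of available features selects all of them
  r3 <- rank_rf_oob(X[, 1:2], y, N = 3, seed = 42)
  expect_length(r3$selected, 2L)
})

test_that("duplicated columns get statistically equivalent RF importance", {
  set.seed(8)
  n <- 60
  sig <- c(rnorm(n / 2, -1, 0.7), rnorm(n / 2, 1, 0.7))
  X <- cbind(s1 = sig, s2 = sig, noise = rnorm(n))
  y <- rep(c(0L, 1L), each = n / 2)
  r <- rank_rf_oob(X, y, seed = 5)
  expect_lt(abs(r$importance["s1"] - r$importance["s2"]), 0.15)
})

test_that("NN ablation of an already-zero input is a no-op", {
  set.seed(4)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(c(0L, 1L), 10)
  fit <- nn_fit(X, y, seed = 6)
  fit$W1[1, ] <- 0
  intact_err <- mean((predict(fit, X) >= 0.5) != y)
  errs <- nn_ablation_errors(fit, X, y)
  expect_equal(errs[1], intact_err)
  expect_length(errs, ncol(X))
})

test_that("L1 ranking puts zero-coefficient features last, halves penalty", {
  set.seed(9)
  n <- 40
  X <- cbind(sig = c(rnorm(n / 2, -2, .5), rnorm(n / 2, 2, .5)),
             n1 = rnorm(n), n2 = rnorm(n))
  X <- scale(X)[, ]
  y <- rep(c(0L, 1L), each = n / 2)
  r <- rank_l1lr(X, y, penalty_strength = 1)
  # the over-strong initial penalty was halved until something survived
  expect_lt(r$penalty, 1)
  zero <- names(r$importance)[r$importance == 0]
  nonzero <- names(r$importance)[r$importance > 0]
  expect_true(all(match(nonzero, r$ranked_features) <
                    min(match(zero, r$ranked_features))))
})
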
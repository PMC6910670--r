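test_that("ROC construction matches its closed forms", {
  r1 <- roc_from_scores(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(r1$auc, 1)
  # all scores identical: a single diagonal segment
  r2 <- roc_from_scores(rep(0.5, 8), rep(c(0, 1), 4))
  expect_equal(r2$auc, 0.5)
  expect_equal(r2$points$fpf, c(0, 1))
  expect_equal(r2$points$tpf, c(0, 1))
  # curve is monotone and anchored at (0,0) and (1,1)
  set.seed(14)
  r3 <- roc_from_scores(runif(20), rep(c(0, 1), 10))
  expect_true(all(diff(r3$points$fpf) >= 0))
  expect_true(all(diff(r3$points$tpf) >= 0))
  expect_equal(unlist(r3$points[1, ]), c(fpf = 0, tpf = 0))
  expect_equal(unlist(r3$points[nrow(r3$points), ]), c(fpf = 1, tpf = 1))
})

test_that("trapezoidal AUC equals the tie-corrected Mann-Whitney statistic", {
  set.seed(15)
  for (k in 1:50) {
    n <- sample(6:20, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    # coarse rounding forces plenty of ties
    scores <- round(runif(n), sample(1:2, 1))
    expect_equal(roc_from_scores(scores, labels)$auc,
                 oracle_auc_mw(scores, labels), tolerance = 1e-12)
  }
})

test_that("LOOCV pools one held-out score per patient", {
  tb <- planted_table(n = 12, seed = 3)
  res <- loocv_pooled_scores(tb, "RF", "NB", N = 2, seed = 9)
  expect_length(res$scores, 12L)
  expect_true(all(res$scores >= 0 & res$scores <= 1))
  expect_length(res$per_fold_selected, 12L)
  # a strongly planted signal is recovered
  expect_gt(roc_from_scores(res$scores, res$labels)$auc, 0.85)
})

test_that("cox_only mode passes all surviving features to the classifier", {
  tb <- planted_table(n = 12, seed = 4)
  res <- loocv_pooled_scores(tb, "cox_only", "NB", N = 1, seed = 9)
  scr <- cox_screen(tb$X[-1, ], tb$survival$os_months[-1],
                    tb$survival$event[-1])
  expect_setequal(res$per_fold_selected[[1]], scr$surviving_features)
})

test_that("the held-out patient's survival record never leaks into its fold", {
  tb <- planted_table(n = 10, seed = 6)
  res1 <- loocv_pooled_scores(tb, "L1LR", "L2LR", N = 2, seed = 5)
  tb2 <- tb
  # flip patient 3's label and survival time entirely
  tb2$survival$os_months[3] <- 40
  tb2$survival$class_label[3] <- 1L - tb2$survival$class_label[3]
  res2 <- loocv_pooled_scores(tb2, "L1LR", "L2LR", N = 2, seed = 5)
  expect_identical(res1$scores[3], res2$scores[3])
})

test_that("the grid covers 21 selector-classifier combinations and is
          reproducible", {
  tbs <- list(synthetic = planted_table(n = 10, seed = 8))
  g1 <- run_grid(tbs, iterations = 1, base_seed = 3)
  g2 <- run_grid(tbs, iterations = 1, base_seed = 3)
  expect_identical(g1$auc, g2$auc)
  s <- summarize_grid(g1, best_N = TRUE)
  expect_equal(nrow(unique(s[, c("selector", "classifier")])), 21L)
  expect_equal(nrow(g1), 21L * 3L)
  # per-fold selections never exceed N
  sels <- attr(g1, "selections")$synthetic$RF[[1]]
  expect_true(all(lengths(sels) <= 3))
})

test_that("paired AUC comparisons reproduce hand-computed t statistics", {
  b <- c(0.5, 0.6, 0.7)
  t1 <- paired_auc_test(b + c(1, 2, 3), b)
  expect_equal(t1$t_statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(t1$df, 2L)
  t2 <- paired_auc_test(b, b + c(1, 2, 3))
  expect_equal(t2$t_statistic, -t1$t_statistic)
  expect_equal(t2$p_value, t1$p_value)
  t3 <- paired_auc_test(b, b)
  expect_equal(t3$t_statistic, 0)
  expect_equal(t3$p_value, 1)
  t4 <- paired_auc_test(b + 1, b)
  expect_true(is.na(t4$p_value))
  expect_match(t4$note, "zero-variance")
})

test_that("selection frequencies count every fold and sort by count", {
  sel <- rep(list(c("a", "b")), 12)
  f <- selection_frequency(sel)
  expect_equal(unname(f), c(12L, 12L))
  expect_equal(names(f), c("a", "b"))
  sel2 <- list(c("x", "y"), c("x", "z"), "x")
  f2 <- selection_frequency(sel2)
  expect_equal(sum(f2), sum(lengths(sel2)))
  expect_equal(names(f2)[1], "x")
  # N prefix restriction
  f3 <- selection_frequency(sel2, N = 1)
  expect_equal(unname(f3["x"]), 3L)
})

test_that("single-class labels are rejected by the ROC", {
  expect_error(roc_from_scores(c(0.1, 0.5, 0.9), c(1, 1, 1)),
               "both classes")
})

test_that("an empty in-fold Cox screen falls back to top-|coefficient|", {
  tb <- planted_table(n = 10, seed = 33)
  # an absurdly strict screen never passes anything
  res <- loocv_pooled_scores(tb, "RF", "NB", N = 2, seed = 3,
                             alpha = 1e-12)
  expect_length(res$fallback_folds, 10L)
  expect_true(all(lengths(res$per_fold_selected) <= 2))
  expect_true(all(is.finite(res$scores)))
})

test_that("train-only normalization rescales inside each fold", {
  tb <- planted_table(n = 10, seed = 34)
  res_whole <- loocv_pooled_scores(tb, "L1LR", "NB", N = 2, seed = 4)
  tb$normalization_scope <- "train_only"
  res_fold <- loocv_pooled_scores(tb, "L1LR", "NB", N = 2, seed = 4)
  expect_true(all(is.finite(res_fold$scores)))
  expect_false(identical(res_whole$scores, res_fold$scores))
})
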
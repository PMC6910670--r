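#' Pooled-score ROC curve with thresholds at all distinct scores
#'
#' For every distinct score value `t`, rows with `score >= t` are called
#' class 1 and the (false, true) positive fractions are recorded; the
#' endpoints (0,0) and (1,1) are appended and the AUC is the trapezoidal
#' integral of the resulting curve. With tied scores this equals the
#' tie-corrected Mann-Whitney statistic U / (n0 * n1).
#'
#' @param scores numeric scores (higher = more class-1-like).
#' @param labels binary 0/1 labels, both classes present.
#' @return An object of class `roc_curve`: list with `points` (data frame
#'   `fpf`, `tpf`), `thresholds` and `auc`.
#' @export
roc_from_scores <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stop_deltarad("`scores` and `labels` lengths differ")
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0)
    stop_deltarad("both classes must be present")
  th <- sort(unique(scores), decreasing = TRUE)
  pts <- t(vapply(th, function(t) {
    pos <- scores >= t
    c(fpf = sum(pos & labels == 0L) / n0,
      tpf = sum(pos & labels == 1L) / n1)
  }, numeric(2)))
  pts <- rbind(c(0, 0), pts, c(1, 1))
  pts <- unique(pts[order(pts[, 1], pts[, 2]), , drop = FALSE])
  auc <- sum(diff(pts[, 1]) * (head(pts[, 2], -1) + pts[-1, 2]) / 2)
  structure(list(points = data.frame(fpf = pts[, 1], tpf = pts[, 2]),
                 thresholds = th, auc = auc),
            class = "roc_curve")
}

det_selectors <- c("L1LR", "cox_only")
det_classifiers <- c("L1LR", "L2LR", "LSVM", "KSVM", "NB")

rank_features <- function(selector, X, y, N, seed, params = list()) {
  switch(selector,
         RF = do.call(rank_rf_oob,
                      c(list(X = X, labels = y, N = N, seed = seed),
                        params)),
         NN = do.call(rank_nn_ablation,
                      c(list(X = X, labels = y, N = N, seed = seed),
                        params)),
         L1LR = do.call(rank_l1lr, c(list(X = X, labels = y, N = N),
                                     params)),
         stop_deltarad("unknown selector: ", selector))
}

#' Leave-one-out cross-validation with in-fold two-step selection
#'
#' For each of the n folds, the univariate Cox screen and the multivariate
#' ranking are run on the n-1 training rows only, a classifier is trained
#' on the selected columns, and the held-out patient is scored; the n
#' held-out scores are pooled in patient order. With
#' `selector = "cox_only"` the ranking step is skipped and all
#' Cox-surviving features feed the classifier. If a fold's Cox screen
#' survives nothing, the fold falls back to the top-`N` features by
#' absolute Cox coefficient (logged in the result).
#'
#' @param table a `feature_table` (normalized, unless its
#'   `normalization_scope` is `"train_only"`, in which case z-scoring is
#'   recomputed inside every fold from the training rows).
#' @param selector `"RF"`, `"NN"`, `"L1LR"` or `"cox_only"`.
#' @param classifier a classifier name or [classifier_spec()].
#' @param N number of features the selector keeps (capped per fold at the
#'   number of surviving features).
#' @param seed base seed; per-fold seeds are derived from it.
#' @param alpha Cox screen threshold (default 0.1).
#' @param cox_cache optional precomputed list of per-fold [cox_screen()]
#'   results (used by [run_grid()] to avoid rescreening).
#' @param selector_params,classifier_params hyperparameter override lists.
#' @return List with `scores` (one pooled score per patient, in row
#'   order), `labels`, `per_fold_selected` (list of per-fold selected
#'   feature names) and `fallback_folds`.
#' @export
loocv_pooled_scores <- function(table, selector, classifier, N = 3L,
                                seed = 1L, alpha = 0.1, cox_cache = NULL,
                                selector_params = list(),
                                classifier_params = list()) {
  stopifnot(inherits(table, "feature_table"))
  X <- table$X
  y <- table$survival$class_label
  n <- nrow(X)
  if (n < 3) stop_deltarad("need at least 3 patients for LOOCV")
  train_scope <- identical(table$normalization_scope, "train_only")
  scores <- rep(NA_real_, n)
  sel_list <- vector("list", n)
  fallback <- integer(0)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    if (length(unique(y[tr])) < 2)
      stop_deltarad("fold ", i, ": training labels are single-class")
    Xtr <- X[tr, , drop = FALSE]
    Xte <- X[i, , drop = FALSE]
    if (train_scope) {
      Xte <- zscore_apply(Xtr, Xte)
      Xtr <- zscore_apply(Xtr, Xtr)
    }
    scr <- if (!is.null(cox_cache)) cox_cache[[i]] else
      cox_screen(Xtr, table$survival$os_months[tr],
                 table$survival$event[tr], alpha = alpha)
    surv_feats <- scr$surviving_features
    if (length(surv_feats) == 0) {
      fallback <- c(fallback, i)
      ranked_all <- names(sort(-abs(scr$coefficients)))
      surv_feats <- head(ranked_all,
                         if (selector == "cox_only") length(ranked_all)
                         else min(N, length(ranked_all)))
    }
    feats <- if (selector == "cox_only") {
      surv_feats
    } else {
      rk <- rank_features(selector, Xtr[, surv_feats, drop = FALSE],
                          y[tr], N = min(N, length(surv_feats)),
                          seed = derive_seed(seed, "rank", i),
                          params = selector_params)
      rk$selected
    }
    spec <- if (inherits(classifier, "classifier_spec")) classifier else
      do.call(classifier_spec,
              c(list(name = classifier,
                     seed = derive_seed(seed, "clf", i)),
                classifier_params))
    model <- train_classifier(spec, Xtr[, feats, drop = FALSE], y[tr])
    scores[i] <- predict_score(model, Xte[, feats, drop = FALSE])
    sel_list[[i]] <- feats
  }
  list(scores = scores, labels = y, per_fold_selected = sel_list,
       fallback_folds = fallback)
}

#' Evaluate the full selector x classifier x category x N grid
#'
#' Runs pooled-score LOOCV for every combination of feature-selection
#' method, classifier, feature category and number of selected features,
#' repeating each cell `iterations` times with per-iteration seeds derived
#' from `base_seed` (only the stochastic stages - random-forest bootstraps
#' and permutations, network initialization - vary across iterations;
#' fully deterministic cells are computed once and replicated). Per-fold
#' Cox screens are shared across all cells of a category.
#'
#' @param tables named list of normalized `feature_table`s (one per
#'   category, e.g. from [assemble_tables()] + [zscore_normalize()]).
#' @param selectors selection methods (default `c("RF", "NN", "L1LR")`;
#'   `"cox_only"` may be included for the screen-only comparison mode).
#' @param classifiers classifier names (default all seven).
#' @param N_range numbers of selected features (default 1:3; ignored for
#'   `"cox_only"`, reported as `NA`).
#' @param iterations repetitions per cell (default 50).
#' @param base_seed integer master seed.
#' @param alpha Cox screen threshold.
#' @param selector_params,classifier_params hyperparameter override lists.
#' @return An object of class `grid_result`: data frame with columns
#'   `category`, `selector`, `classifier`, `N`, `iteration`, `auc`, plus a
#'   `selections` attribute (nested list
#'   `[[category]][[selector]][[iteration]][[fold]]` of selected-feature
#'   rankings) for the frequency reports.
#' @export
run_grid <- function(tables, selectors = c("RF", "NN", "L1LR"),
                     classifiers = classifier_names(), N_range = 1:3,
                     iterations = 50L, base_seed = 1L, alpha = 0.1,
                     selector_params = list(),
                     classifier_params = list()) {
  rows <- list()
  selections <- list()
  maxN <- max(N_range)
  for (cat in names(tables)) {
    tbl <- tables[[cat]]
    X <- tbl$X
    y <- tbl$survival$class_label
    n <- nrow(X)
    cox_cache <- lapply(seq_len(n), function(i) {
      tr <- setdiff(seq_len(n), i)
      cox_screen(X[tr, , drop = FALSE], tbl$survival$os_months[tr],
                 tbl$survival$event[tr], alpha = alpha)
    })
    selections[[cat]] <- list()
    for (sel in selectors) {
      det_sel <- sel %in% det_selectors
      # rank_cache[[it]][[fold]]: ranked features (length <= maxN), or all
      # surviving features for cox_only
      rank_cache <- vector("list", iterations)
      for (it in seq_len(iterations)) {
        if (det_sel && it > 1L) {
          rank_cache[[it]] <- rank_cache[[1L]]
          next
        }
        rank_cache[[it]] <- lapply(seq_len(n), function(i) {
          tr <- setdiff(seq_len(n), i)
          scr <- cox_cache[[i]]
          sf <- scr$surviving_features
          if (length(sf) == 0)
            sf <- head(names(sort(-abs(scr$coefficients))),
                       if (sel == "cox_only") ncol(X) else maxN)
          if (sel == "cox_only") return(sf)
          rank_features(sel, X[tr, sf, drop = FALSE], y[tr],
                        N = min(maxN, length(sf)),
                        seed = derive_seed(base_seed, cat, sel, it, i),
                        params = selector_params)$selected
        })
      }
      selections[[cat]][[sel]] <- rank_cache
      Ns <- if (sel == "cox_only") NA_integer_ else N_range
      for (cl in classifiers) {
        det_cell <- det_sel && cl %in% det_classifiers
        for (N in Ns) {
          aucs <- numeric(iterations)
          for (it in seq_len(iterations)) {
            if (det_cell && it > 1L) {
              aucs[it] <- aucs[1L]
              next
            }
            sc <- vapply(seq_len(n), function(i) {
              tr <- setdiff(seq_len(n), i)
              feats <- rank_cache[[it]][[i]]
              if (!is.na(N)) feats <- head(feats, N)
              spec <- do.call(classifier_spec, c(
                list(name = cl,
                     seed = derive_seed(base_seed, cat, sel, cl, N, it, i)),
                classifier_params))
              m <- train_classifier(spec, X[tr, feats, drop = FALSE],
                                    y[tr])
              predict_score(m, X[i, feats, drop = FALSE])
            }, numeric(1))
            aucs[it] <- roc_from_scores(sc, y)$auc
          }
          rows[[length(rows) + 1L]] <- data.frame(
            category = cat, selector = sel, classifier = cl, N = N,
            iteration = seq_len(iterations), auc = aucs,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "selections") <- selections
  attr(out, "iterations") <- iterations
  class(out) <- c("grid_result", class(out))
  out
}

#' Per-cell mean AUCs and the best-N summary
#'
#' Averages AUC over iterations for each (category, selector, classifier,
#' N) cell and, when `best_N = TRUE`, keeps for each (category, selector,
#' classifier) the cell with the highest mean AUC over the tested numbers
#' of selected features (the convention used to report one AUC per model
#' combination).
#'
#' @param grid a [run_grid()] result.
#' @param best_N collapse over `N` (default `FALSE`).
#' @return Data frame with `mean_auc` (and `sd_auc`) per cell.
#' @export
summarize_grid <- function(grid, best_N = FALSE) {
  grid <- as.data.frame(grid)
  # aggregate() drops NA grouping levels; cox_only cells carry N = NA
  grid$N[is.na(grid$N)] <- -1L
  agg <- aggregate(auc ~ category + selector + classifier + N, data = grid,
                   FUN = mean)
  names(agg)[names(agg) == "auc"] <- "mean_auc"
  sdv <- aggregate(auc ~ category + selector + classifier + N, data = grid,
                   FUN = stats::sd)
  agg$sd_auc <- sdv$auc
  agg$N[agg$N == -1L] <- NA_integer_
  if (best_N) {
    split_keys <- interaction(agg$category, agg$selector, agg$classifier)
    agg <- do.call(rbind, lapply(split(agg, split_keys), function(d) {
      d[which.max(d$mean_auc), , drop = FALSE]
    }))
    rownames(agg) <- NULL
  }
  agg[order(agg$category, agg$selector, agg$classifier, agg$N), ,
      drop = FALSE]
}

#' Paired-sample t-test between two aligned mean-AUC vectors
#'
#' Two-sided paired t-test across model combinations (the 21
#' selector-classifier pairs in the full design). All-zero differences
#' give `t = 0`, `p = 1`; nonzero constant differences have undefined
#' variance and are reported with `p = NA` and a note.
#'
#' @param auc_a,auc_b equal-length mean-AUC vectors aligned by model
#'   combination.
#' @return List with `t_statistic`, `df`, `p_value`, `mean_difference`
#'   and possibly `note`.
#' @export
paired_auc_test <- function(auc_a, auc_b) {
  if (length(auc_a) != length(auc_b) || length(auc_a) < 2)
    stop_deltarad("need two aligned vectors of length >= 2")
  d <- auc_a - auc_b
  if (sd(d) == 0) {
    if (all(d == 0))
      return(list(t_statistic = 0, df = length(d) - 1L, p_value = 1,
                  mean_difference = 0))
    return(list(t_statistic = sign(mean(d)) * Inf, df = length(d) - 1L,
                p_value = NA_real_, mean_difference = mean(d),
                note = "zero-variance nonzero differences"))
  }
  tt <- t.test(auc_a, auc_b, paired = TRUE)
  list(t_statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_difference = unname(tt$estimate))
}

#' Selection frequency of features across folds and iterations
#'
#' @param per_fold_selected list (arbitrarily nested) of character vectors
#'   of selected feature names, e.g. from
#'   `attr(run_grid(...), "selections")` or
#'   [loocv_pooled_scores()]`$per_fold_selected`.
#' @param N optional: count only the top-`N` of each ranking.
#' @return Named integer vector of counts, sorted decreasing (ties by
#'   name).
#' @export
selection_frequency <- function(per_fold_selected, N = NULL) {
  flat <- if (is.null(N)) {
    unlist(per_fold_selected, use.names = FALSE)
  } else {
    rapply(per_fold_selected, function(v) head(v, N), how = "unlist")
  }
  if (length(flat) == 0) stop_deltarad("no selections supplied")
  tab <- table(flat)
  cnt <- as.integer(tab)
  names(cnt) <- names(tab)
  cnt[order(-cnt, names(cnt))]
}
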
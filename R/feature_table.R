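#' Relative-change delta features between two time points
#'
#' Computes the per-feature relative change `(F_post - F_pre) / F_pre` on
#' the raw (pre-normalization) scale. Entries whose baseline magnitude is
#' below `eps` are marked undefined (`NA`) and listed in the
#' `undefined_features` attribute, since the ratio is numerically unbounded
#' there.
#'
#' @param f_pre,f_post named numeric vectors (e.g. [extract_all()] results)
#'   with identical names.
#' @param eps baseline magnitude below which the delta is undefined
#'   (default 1e-9).
#' @return Named numeric vector of deltas with attributes
#'   `undefined_features` and `delta_kind`.
#' @export
compute_delta <- function(f_pre, f_post, eps = 1e-9) {
  if (!identical(names(f_pre), names(f_post)))
    stop_deltarad("feature names of `f_pre` and `f_post` differ")
  pre <- as.numeric(f_pre)
  post <- as.numeric(f_post)
  delta <- (post - pre) / pre
  undef <- !is.na(pre) & abs(pre) < eps
  delta[undef] <- NA_real_
  structure(setNames(delta, names(f_pre)),
            undefined_features = names(f_pre)[undef],
            delta_kind = attr(f_post, "timepoint") %||% NA_character_)
}

#' Assemble the five analysis-ready feature tables
#'
#' Builds one patients-x-features table per category: the three
#' single-time-point categories `F_pre`, `F_post1`, `F_post2` (T1 and
#' T2-FLAIR features concatenated with modality prefixes, 2 x 61 = 122
#' columns before dropping) and the two delta categories `dF1`, `dF2`
#' (relative change of post1/post2 vs pre). Columns that are all-zero, have
#' any undefined (`NA`) entry, or are constant across patients are dropped
#' and logged in the `dropped` attribute of each table; with a shared GTV
#' mask all morphological deltas are exactly zero and drop from the delta
#' tables. Row order follows sorted `patient_id`, independent of input
#' order.
#'
#' @param features data frame from [extract_cohort()].
#' @param survival survival data frame (`patient_id`, `os_months`, `event`,
#'   `class_label`).
#' @param eps baseline threshold passed to [compute_delta()].
#' @return Named list of five `feature_table` objects (`F_pre`, `F_post1`,
#'   `F_post2`, `dF1`, `dF2`), each a list with `category`, `X` (numeric
#'   matrix), `feature_names`, `survival`, `normalized` flag and `dropped`
#'   log (data frame `name`/`reason`).
#' @export
assemble_tables <- function(features, survival, eps = 1e-9) {
  fnames <- feature_registry()$name
  ids <- sort(unique(survival$patient_id))
  mods <- c("T1", "T2FLAIR")
  tps <- c("pre", "post1", "post2")
  # feat[[mod]][[tp]] = patients x 61 matrix in sorted-patient order
  feat <- list()
  for (mod in mods) {
    feat[[mod]] <- list()
    for (tp in tps) {
      sub <- features[features$modality == mod & features$timepoint == tp, ,
                      drop = FALSE]
      missing <- setdiff(ids, sub$patient_id)
      if (length(missing) > 0)
        stop_deltarad("missing (patient, modality, timepoint): ",
                      paste(missing, mod, tp, collapse = "; "))
      sub <- sub[match(ids, sub$patient_id), , drop = FALSE]
      m <- as.matrix(sub[, fnames, drop = FALSE])
      rownames(m) <- ids
      feat[[mod]][[tp]] <- m
    }
  }
  surv <- survival[match(ids, survival$patient_id), , drop = FALSE]
  rownames(surv) <- NULL

  single <- function(tp) {
    do.call(cbind, lapply(mods, function(mod) {
      m <- feat[[mod]][[tp]]
      colnames(m) <- paste(mod, colnames(m), sep = "_")
      m
    }))
  }
  delta <- function(tp) {
    do.call(cbind, lapply(mods, function(mod) {
      pre <- feat[[mod]][["pre"]]
      post <- feat[[mod]][[tp]]
      d <- (post - pre) / pre
      d[abs(pre) < eps] <- NA_real_
      colnames(d) <- paste(mod, colnames(d), sep = "_")
      d
    }))
  }
  mats <- list(F_pre = single("pre"), F_post1 = single("post1"),
               F_post2 = single("post2"), dF1 = delta("post1"),
               dF2 = delta("post2"))
  lapply(setNames(names(mats), names(mats)), function(cat) {
    new_feature_table(cat, mats[[cat]], surv)
  })
}

new_feature_table <- function(category, X, survival, normalized = FALSE) {
  has_na <- apply(X, 2, function(col) any(!is.finite(col)))
  all_zero <- !has_na & apply(X, 2, function(col) all(col == 0))
  bad <- has_na | all_zero
  dropped <- data.frame(
    name = colnames(X)[bad],
    reason = ifelse(has_na[bad], "undefined", "all_zero"),
    stringsAsFactors = FALSE)
  X <- X[, !bad, drop = FALSE]
  structure(list(category = category, X = X,
                 feature_names = colnames(X), survival = survival,
                 normalized = normalized, dropped = dropped),
            class = "feature_table")
}

#' Z-score normalize a feature table
#'
#' Column-wise `(x - mean) / sd` with the population (n-denominator)
#' standard deviation. The default scope normalizes over the whole dataset
#' before any cross-validation split; `train_only` is available for
#' sensitivity analyses and is applied per fold inside
#' [loocv_pooled_scores()]. Constant columns cannot be scaled and are
#' dropped with a warning (and logged).
#'
#' @param table a `feature_table`.
#' @param scope `"whole_dataset"` (default) or `"train_only"` (recorded on
#'   the table; the per-fold recomputation happens in the evaluation loop).
#' @return The normalized `feature_table` (idempotent up to 1e-9).
#' @export
zscore_normalize <- function(table, scope = c("whole_dataset",
                                              "train_only")) {
  scope <- match.arg(scope)
  stopifnot(inherits(table, "feature_table"))
  X <- table$X
  if (nrow(X) < 2) stop_deltarad("need at least 2 rows to normalize")
  mu <- colMeans(X)
  sdev <- sqrt(colMeans(sweep(X, 2, mu)^2))
  const <- sdev <= 0
  if (any(const)) {
    warning(sum(const), " constant column(s) dropped during z-scoring")
    table$dropped <- rbind(table$dropped,
                           data.frame(name = colnames(X)[const],
                                      reason = "constant",
                                      stringsAsFactors = FALSE))
    X <- X[, !const, drop = FALSE]
    mu <- mu[!const]
    sdev <- sdev[!const]
  }
  table$X <- sweep(sweep(X, 2, mu), 2, sdev, `/`)
  table$feature_names <- colnames(table$X)
  table$normalized <- TRUE
  table$normalization_scope <- scope
  table
}

# z-score X_apply using mean/population-sd computed from X_ref rows
zscore_apply <- function(X_ref, X_apply) {
  mu <- colMeans(X_ref)
  sdev <- sqrt(colMeans(sweep(X_ref, 2, mu)^2))
  sdev[sdev <= 0] <- 1
  sweep(sweep(X_apply, 2, mu), 2, sdev, `/`)
}
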
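# Shared fixture builders (all data generated in code at test time).

# a quantized_roi with random integer levels on a random mask
rand_quantized_roi <- function(dims, G = 4, seed = 1, mask_prob = 0.8) {
  set.seed(seed)
  mask <- array(runif(prod(dims)) < mask_prob, dims)
  if (!any(mask)) mask[1] <- TRUE
  levels <- array(0L, dims)
  levels[mask] <- sample.int(G, sum(mask), replace = TRUE)
  structure(list(levels = levels, mask = mask, G = as.integer(G),
                 spacing = c(1, 1, 1), degenerate = FALSE),
            class = "quantized_roi")
}

const_quantized_roi <- function(dims, G = 64) {
  levels <- array(1L, dims)
  structure(list(levels = levels, mask = array(TRUE, dims),
                 G = as.integer(G), spacing = c(1, 1, 1),
                 degenerate = TRUE),
            class = "quantized_roi")
}

# a ready-made feature_table with one informative ("planted") column among
# pure-noise columns, and survival records consistent with the class label.
# The planted column follows the class-conditional Gaussian construction
# used throughout the selection tests: class means +/- shift/2, sd 0.5.
planted_table <- function(n = 12, p_noise = 9, shift = 3, seed = 1,
                          planted_name = "planted") {
  set.seed(seed)
  y <- sample(rep(c(0L, 1L), length.out = n))
  X <- matrix(rnorm(n * p_noise), n, p_noise,
              dimnames = list(NULL, sprintf("noise%02d", seq_len(p_noise))))
  X <- cbind(X, rnorm(n, (y - 0.5) * shift, 0.5))
  colnames(X)[p_noise + 1] <- planted_name
  X <- X[, order(colnames(X)), drop = FALSE]
  mu <- colMeans(X)
  sdp <- sqrt(colMeans(sweep(X, 2, mu)^2))
  X <- sweep(sweep(X, 2, mu), 2, sdp, `/`)
  os <- ifelse(y == 1L, runif(n, 12, 29.4), runif(n, 5.3, 12))
  surv <- data.frame(patient_id = sprintf("P%02d", seq_len(n)),
                     os_months = os, event = 1L, class_label = y,
                     stringsAsFactors = FALSE)
  structure(list(category = "synthetic", X = X,
                 feature_names = colnames(X), survival = surv,
                 normalized = TRUE,
                 dropped = data.frame(name = character(0),
                                      reason = character(0))),
            class = "feature_table")
}

# small imaging cohort reused across test files (computed once per session)
.fixture_env <- new.env(parent = emptyenv())

small_cohort <- function(effect_size = 4, seed = 101) {
  key <- paste0("cohort_", effect_size, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    cfg <- cohort_config(n_patients = 8L, grid_shape = c(20L, 20L, 20L),
                         mask_radius_vox = 4.4, effect_size = effect_size,
                         seed = seed)
    .fixture_env[[key]] <- generate_cohort(cfg)
  }
  .fixture_env[[key]]
}

small_cohort_tables <- function(effect_size = 4, seed = 101) {
  key <- paste0("tables_", effect_size, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    ch <- small_cohort(effect_size, seed)
    feats <- extract_cohort(ch$patients)
    tabs <- assemble_tables(feats, ch$survival)
    .fixture_env[[key]] <- suppressWarnings(lapply(tabs, zscore_normalize))
  }
  .fixture_env[[key]]
}
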
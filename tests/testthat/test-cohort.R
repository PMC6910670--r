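test_that("cohort generation is deterministic given the seed", {
  cfg <- cohort_config(n_patients = 4L, grid_shape = c(16L, 16L, 16L),
                       mask_radius_vox = 4, seed = 3L)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$survival, c2$survival)
  expect_identical(c1$patients[[2]]$volumes$T1_post1$voxels,
                   c2$patients[[2]]$volumes$T1_post1$voxels)
  cfg2 <- cohort_config(n_patients = 4L, grid_shape = c(16L, 16L, 16L),
                        mask_radius_vox = 4, seed = 4L)
  c3 <- generate_cohort(cfg2)
  expect_false(identical(c1$patients[[1]]$volumes$T1_pre$voxels,
                         c3$patients[[1]]$volumes$T1_pre$voxels))
})

test_that("survival records dichotomize OS at 12 months", {
  ch <- small_cohort()
  s <- ch$survival
  expect_identical(s$class_label, as.integer(s$os_months >= 12))
  expect_true(all(s$os_months >= 5.3 & s$os_months <= 29.4))
  expect_equal(sum(s$class_label), round(nrow(s) * 0.5))
  expect_true(all(s$event == 1L))

  cfg <- cohort_config(n_patients = 12L, grid_shape = c(16L, 16L, 16L),
                       mask_radius_vox = 4, censoring_fraction = 0.25,
                       seed = 9L)
  cc <- generate_cohort(cfg)
  expect_equal(sum(cc$survival$event == 0L), 3L)
})

test_that("configurations whose mask falls below 100 voxels are rejected", {
  cfg <- cohort_config(grid_shape = c(10L, 10L, 10L), mask_radius_vox = 2,
                       seed = 1L)
  expect_error(generate_cohort(cfg), "100 voxels")
  expect_error(cohort_config(n_patients = 2), "at least 3")
  expect_error(cohort_config(effect_size = -1), ">= 0")
  expect_error(cohort_config(class_balance = 1), "class_balance")
})

test_that("the planted effect acts only on class-1 post-treatment T1", {
  cfg0 <- cohort_config(n_patients = 6L, grid_shape = c(16L, 16L, 16L),
                        mask_radius_vox = 4, effect_size = 0, seed = 21L)
  cfg4 <- cohort_config(n_patients = 6L, grid_shape = c(16L, 16L, 16L),
                        mask_radius_vox = 4, effect_size = 4, seed = 21L)
  c0 <- generate_cohort(cfg0)
  c4 <- generate_cohort(cfg4)
  expect_identical(c0$survival, c4$survival)
  for (p in seq_along(c0$patients)) {
    v0 <- c0$patients[[p]]$volumes
    v4 <- c4$patients[[p]]$volumes
    mask <- c0$patients[[p]]$gtv_mask
    # pre-treatment images never depend on the class label or effect size
    expect_identical(v0$T1_pre$voxels, v4$T1_pre$voxels)
    expect_identical(v0$T2FLAIR_pre$voxels, v4$T2FLAIR_pre$voxels)
    if (c0$survival$class_label[p] == 0L) {
      expect_identical(v0$T1_post1$voxels, v4$T1_post1$voxels)
      expect_identical(v0$T1_post2$voxels, v4$T1_post2$voxels)
    } else {
      # perturbed inside the GTV only
      expect_false(identical(v0$T1_post1$voxels[mask],
                             v4$T1_post1$voxels[mask]))
      expect_identical(v0$T1_post1$voxels[!mask],
                       v4$T1_post1$voxels[!mask])
    }
    expect_identical(v0$T2FLAIR_post1$voxels, v4$T2FLAIR_post1$voxels)
  }
})

test_that("with no planted effect, delta features are class-independent", {
  d1 <- d0 <- numeric(0)
  for (seed in 1:6) {
    cfg <- cohort_config(n_patients = 8L, grid_shape = c(16L, 16L, 16L),
                         mask_radius_vox = 4, effect_size = 0, seed = seed)
    ch <- generate_cohort(cfg)
    for (p in seq_along(ch$patients)) {
      pat <- ch$patients[[p]]
      fpre <- extract_all(pat$volumes$T1_pre, pat$gtv_mask)
      fpost <- extract_all(pat$volumes$T1_post1, pat$gtv_mask)
      d <- (fpost["GLCOM_contrast"] - fpre["GLCOM_contrast"]) /
        fpre["GLCOM_contrast"]
      if (ch$survival$class_label[p] == 1L) d1 <- c(d1, d) else
        d0 <- c(d0, d)
    }
  }
  expect_gt(suppressWarnings(stats::ks.test(d1, d0)$p.value), 0.05)
})

test_that("class separation of the planted delta grows with effect size", {
  effects <- c(0, 0.5, 1, 2, 4)
  seeds <- 1:20
  smd <- matrix(NA_real_, length(seeds), length(effects))
  for (si in seq_along(seeds)) {
    for (ei in seq_along(effects)) {
      cfg <- cohort_config(n_patients = 8L, grid_shape = c(16L, 16L, 16L),
                           mask_radius_vox = 4, effect_size = effects[ei],
                           seed = 300L + seeds[si])
      ch <- generate_cohort(cfg)
      d <- vapply(ch$patients, function(pat) {
        fpre <- glcom_features(quantize_roi(pat$volumes$T1_pre,
                                            pat$gtv_mask))
        fpost <- glcom_features(quantize_roi(pat$volumes$T1_post1,
                                             pat$gtv_mask))
        unname((fpost["GLCOM_contrast"] - fpre["GLCOM_contrast"]) /
                 fpre["GLCOM_contrast"])
      }, numeric(1))
      y <- ch$survival$class_label
      smd[si, ei] <- abs(mean(d[y == 1]) - mean(d[y == 0])) / stats::sd(d)
    }
  }
  m <- colMeans(smd)
  se <- apply(smd, 2, stats::sd) / sqrt(length(seeds))
  for (k in seq_len(length(effects) - 1)) {
    expect_gte(m[k + 1], m[k] - 2 * (se[k] + se[k + 1]))
  }
  # and the largest effect clearly separates
  expect_gt(m[length(effects)], m[1])
})

test_that("at effect size 3 some contrast-type delta feature has AUC > 0.8", {
  cfg <- cohort_config(n_patients = 40L, effect_size = 3, seed = 77L)
  ch <- generate_cohort(cfg)
  feats <- extract_cohort(ch$patients)
  tabs <- assemble_tables(feats, ch$survival)
  tb <- tabs$dF1
  y <- tb$survival$class_label
  cand <- intersect(c("T1_GLCOM_contrast", "T1_GLCOM_dissimilarity",
                      "T1_GLCOM_difference_average"), colnames(tb$X))
  aucs <- vapply(cand, function(f)
    roc_from_scores(tb$X[, f], y)$auc, numeric(1))
  expect_gt(max(aucs), 0.8)
})

test_that("cohorts round-trip through NIfTI + CSV byte-faithfully", {
  ch <- small_cohort(effect_size = 2, seed = 55)
  dir <- withr::local_tempdir()
  manifest <- write_cohort(ch, dir)
  nii <- list.files(dir, pattern = "\\.nii\\.gz$")
  # 6 volumes + 1 mask per patient
  expect_length(nii, length(ch$patients) * 7L)
  expect_true(file.exists(file.path(dir, "survival.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_equal(manifest$n_patients, length(ch$patients))

  back <- read_cohort(dir)
  expect_equal(back$survival$os_months, ch$survival$os_months,
               tolerance = 1e-12)
  v_in <- ch$patients[[1]]$volumes$T1_post1$voxels
  v_out <- back$patients[[1]]$volumes$T1_post1$voxels
  # float32 storage: read-back equals the float32 representation exactly
  expect_identical(dim(v_in), dim(v_out))
  expect_equal(v_out, v_in, tolerance = 1e-6)
  expect_identical(back$patients[[1]]$gtv_mask, ch$patients[[1]]$gtv_mask)
})

test_that("writing a cohort to an unwritable location fails cleanly", {
  ch <- small_cohort()
  expect_error(write_cohort(ch, "/proc/definitely/not/writable"))
})
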
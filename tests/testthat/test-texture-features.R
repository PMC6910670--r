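test_that("feature families have the documented cardinalities", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 61L)
  expect_equal(as.integer(table(reg$family)[c("GLCOM", "GLRLM", "GLSZM",
                                              "NGLDM", "MORPH", "HIST")]),
               c(22L, 11L, 13L, 5L, 6L, 4L))
  q <- rand_quantized_roi(c(4, 4, 4), G = 4, seed = 1)
  expect_length(glcom_features(q), 22L)
  expect_length(glrlm_features(q), 11L)
  expect_length(glszm_features(q), 13L)
  expect_length(ngldm_features(q), 5L)
})

test_that("a constant ROI hits the degenerate closed forms", {
  q <- const_quantized_roi(c(3, 3, 3))
  gl <- glcom_features(q)
  expect_equal(unname(gl["GLCOM_energy"]), 1)
  expect_equal(unname(gl["GLCOM_entropy"]), 0)
  expect_equal(unname(gl["GLCOM_contrast"]), 0)
  expect_equal(unname(gl["GLCOM_dissimilarity"]), 0)
  expect_equal(unname(gl["GLCOM_correlation"]), 0)

  ng <- ngldm_features(q)
  expect_equal(unname(ng["NGLDM_contrast"]), 0)
  expect_equal(unname(ng["NGLDM_busyness"]), 0)
  expect_equal(unname(ng["NGLDM_texture_strength"]), 0)
  expect_true(is.finite(ng["NGLDM_coarseness"]))

  # one zone of n voxels
  gz <- glszm_features(q)
  expect_equal(unname(gz["GLSZM_zone_percentage"]), 1 / 27)
  expect_equal(unname(gz["GLSZM_zone_size_variance"]), 0)
  expect_equal(unname(gz["GLSZM_grey_level_variance"]), 0)
})

test_that("a single-voxel ROI yields flagged NA co-occurrence features", {
  q <- structure(list(levels = array(1L, c(1, 1, 1)),
                      mask = array(TRUE, c(1, 1, 1)), G = 64L,
                      spacing = c(1, 1, 1), degenerate = TRUE),
                 class = "quantized_roi")
  f <- glcom_features(q)
  expect_true(all(is.na(f)))
  expect_true(attr(f, "degenerate"))
})

test_that("a single straight run matches its closed forms", {
  q <- const_quantized_roi(c(1, 1, 5))
  along <- matrix(c(0L, 0L, 1L), 1)
  f <- glrlm_features(q, directions = along)
  expect_equal(unname(f["GLRLM_long_run_emphasis"]), 25)
  expect_equal(unname(f["GLRLM_short_run_emphasis"]), 1 / 25)
  expect_equal(unname(f["GLRLM_run_percentage"]), 1 / 5)
})

test_that("zones of a hand-built pattern are found with 26-connectivity", {
  # two diagonal voxels of level 2 touch only at a corner: one 26-connected
  # zone; an isolated level-1 voxel makes a second zone
  lv <- array(0L, c(3, 3, 1))
  lv[1, 1, 1] <- 2L
  lv[2, 2, 1] <- 2L
  lv[3, 1, 1] <- 1L
  q <- structure(list(levels = lv, mask = lv > 0, G = 2L,
                      spacing = c(1, 1, 1), degenerate = FALSE),
                 class = "quantized_roi")
  z <- glszm_zones(q)
  z <- z[order(z[, "level"], z[, "size"]), , drop = FALSE]
  expect_equal(unname(z[, "level"]), c(1L, 2L))
  expect_equal(unname(z[, "size"]), c(1L, 2L))
})

test_that("texture features match brute-force enumeration oracles", {
  for (seed in 1:8) {
    dims <- c(sample(2:5, 1), sample(2:5, 1), sample(1:4, 1))
    G <- sample(2:6, 1)
    q <- rand_quantized_roi(dims, G = G, seed = seed)
    expect_equal(as.numeric(glcom_features(q)),
                 as.numeric(oracle_glcom_features(q$levels, G)),
                 tolerance = 1e-12)
    expect_equal(as.numeric(glrlm_features(q)),
                 as.numeric(oracle_glrlm_features(q$levels)),
                 tolerance = 1e-12)
    expect_equal(as.numeric(glszm_features(q)),
                 as.numeric(oracle_glszm_features(q$levels)),
                 tolerance = 1e-12)
    expect_equal(as.numeric(ngldm_features(q)),
                 as.numeric(oracle_ngldm_features(q$levels, G)),
                 tolerance = 1e-12)
  }
})
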
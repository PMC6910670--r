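#' Grey-level co-occurrence matrix of a quantized ROI
#'
#' Accumulates a single symmetric co-occurrence matrix over distance-1 voxel
#' pairs restricted to the mask, summed across directions (by default the 13
#' unique 3D directions of the 26-neighbourhood), then optionally normalized
#' to probabilities.
#'
#' @param q a [quantize_roi()] result.
#' @param directions integer matrix of direction offsets (rows of
#'   `(dx, dy, dz)`); default all 13 unique 3D directions.
#' @param normalize return probabilities (`TRUE`) or pair counts.
#' @return `G x G` matrix.
#' @export
glcm_matrix <- function(q, directions = unique_directions_3d(),
                        normalize = TRUE) {
  check_quantized(q)
  m <- .glcm_counts_cpp(as.integer(q$levels), dim(q$levels), q$G, directions)
  if (normalize && sum(m) > 0) m <- m / sum(m)
  m
}

#' The 22 co-occurrence (GLCOM) texture features
#'
#' Computes 22 features from the probability-normalized symmetric
#' co-occurrence matrix: energy, entropy, contrast, dissimilarity,
#' homogeneity (inverse difference), inverse difference moment (plus
#' normalized variants of both), correlation, autocorrelation, cluster
#' tendency/shade/prominence, maximum probability, joint average, joint
#' variance, and the sum/difference histogram statistics. Log terms use base
#' 2. Correlation of a zero-variance (single-level) ROI is defined as 0.
#'
#' @inheritParams glcm_matrix
#' @return Named numeric vector of length 22. A single-voxel ROI (no valid
#'   pairs) yields all-`NA` values with attribute `degenerate = TRUE`.
#' @export
glcom_features <- function(q, directions = unique_directions_3d()) {
  counts <- glcm_matrix(q, directions, normalize = FALSE)
  nm <- feature_names_glcom()
  if (sum(counts) == 0) {
    out <- setNames(rep(NA_real_, length(nm)), nm)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  p <- counts / sum(counts)
  G <- nrow(p)
  I <- matrix(seq_len(G), G, G)
  J <- t(I)
  px <- rowSums(p)
  mu <- sum(seq_len(G) * px)
  sigma2 <- sum((seq_len(G) - mu)^2 * px)
  ent <- function(v) {
    v <- v[v > 0]
    -sum(v * log2(v))
  }
  # sum (k = i + j) and difference (k = |i - j|) histograms
  psum <- tapply(as.vector(p), as.vector(I + J), sum)
  ks <- as.numeric(names(psum))
  pdiff <- tapply(as.vector(p), as.vector(abs(I - J)), sum)
  kd <- as.numeric(names(pdiff))
  sum_avg <- sum(ks * psum)
  diff_avg <- sum(kd * pdiff)
  out <- c(
    GLCOM_energy = sum(p^2),
    GLCOM_entropy = ent(p),
    GLCOM_contrast = sum((I - J)^2 * p),
    GLCOM_dissimilarity = sum(abs(I - J) * p),
    GLCOM_homogeneity = sum(p / (1 + abs(I - J))),
    GLCOM_inverse_difference_moment = sum(p / (1 + (I - J)^2)),
    GLCOM_inverse_difference_moment_normalized =
      sum(p / (1 + ((I - J) / G)^2)),
    GLCOM_inverse_difference_normalized = sum(p / (1 + abs(I - J) / G)),
    GLCOM_correlation =
      if (sigma2 > 1e-12) (sum(I * J * p) - mu^2) / sigma2 else 0,
    GLCOM_autocorrelation = sum(I * J * p),
    GLCOM_cluster_tendency = sum((I + J - 2 * mu)^2 * p),
    GLCOM_cluster_shade = sum((I + J - 2 * mu)^3 * p),
    GLCOM_cluster_prominence = sum((I + J - 2 * mu)^4 * p),
    GLCOM_maximum_probability = max(p),
    GLCOM_joint_average = mu,
    GLCOM_joint_variance = sum((I - mu)^2 * p),
    GLCOM_sum_average = sum_avg,
    GLCOM_sum_variance = sum((ks - sum_avg)^2 * psum),
    GLCOM_sum_entropy = ent(psum),
    GLCOM_difference_average = diff_avg,
    GLCOM_difference_variance = sum((kd - diff_avg)^2 * pdiff),
    GLCOM_difference_entropy = ent(pdiff)
  )
  stopifnot(identical(names(out), nm))
  out
}

#' Grey-level run-length matrix of a quantized ROI
#'
#' Runs are maximal collinear sequences of in-mask voxels sharing a grey
#' level; run-length matrices are accumulated (summed) over the given
#' directions.
#'
#' @inheritParams glcm_matrix
#' @return `G x Lmax` matrix of run counts (trailing all-zero length columns
#'   trimmed).
#' @export
glrlm_matrix <- function(q, directions = unique_directions_3d()) {
  check_quantized(q)
  m <- .glrlm_counts_cpp(as.integer(q$levels), dim(q$levels), q$G, directions)
  last <- max(c(1L, which(colSums(m) > 0)))
  m[, seq_len(last), drop = FALSE]
}

#' The 11 run-length (GLRLM) texture features
#'
#' Short/long run emphasis, grey-level and run-length non-uniformity, run
#' percentage and the four joint low/high grey-level run-emphasis features,
#' computed from the direction-summed run-length matrix. Run percentage uses
#' the total number of in-mask voxels times the number of directions as its
#' denominator, so a single-direction call on a straight line of length L
#' gives `RP = 1/L`.
#'
#' @inheritParams glcm_matrix
#' @return Named numeric vector of length 11.
#' @export
glrlm_features <- function(q, directions = unique_directions_3d()) {
  check_quantized(q)
  m <- glrlm_matrix(q, directions)
  nr <- sum(m)
  nvox <- sum(q$mask)
  i <- seq_len(nrow(m))
  j <- seq_len(ncol(m))
  ri <- rowSums(m)
  rj <- colSums(m)
  I2 <- matrix(i^2, nrow(m), ncol(m))
  J2 <- matrix(j^2, nrow(m), ncol(m), byrow = TRUE)
  out <- c(
    GLRLM_short_run_emphasis = sum(rj / j^2) / nr,
    GLRLM_long_run_emphasis = sum(rj * j^2) / nr,
    GLRLM_grey_level_nonuniformity = sum(ri^2) / nr,
    GLRLM_run_length_nonuniformity = sum(rj^2) / nr,
    GLRLM_run_percentage = nr / (nvox * nrow(directions)),
    GLRLM_low_grey_level_run_emphasis = sum(ri / i^2) / nr,
    GLRLM_high_grey_level_run_emphasis = sum(ri * i^2) / nr,
    GLRLM_short_run_low_grey_level_emphasis = sum(m / (I2 * J2)) / nr,
    GLRLM_short_run_high_grey_level_emphasis = sum(m * I2 / J2) / nr,
    GLRLM_long_run_low_grey_level_emphasis = sum(m * J2 / I2) / nr,
    GLRLM_long_run_high_grey_level_emphasis = sum(m * I2 * J2) / nr
  )
  stopifnot(identical(names(out), feature_names_glrlm()))
  out
}

#' Size zones of a quantized ROI
#'
#' Zones are 26-connected components of equal grey level within the mask.
#'
#' @inheritParams glcm_matrix
#' @return Two-column integer matrix `(level, size)`, one row per zone.
#' @export
glszm_zones <- function(q) {
  check_quantized(q)
  z <- .glszm_zones_cpp(as.integer(q$levels), dim(q$levels))
  colnames(z) <- c("level", "size")
  z
}

#' The 13 size-zone (GLSZM) texture features
#'
#' Small/large zone emphasis, grey-level and zone-size non-uniformity, zone
#' percentage, the four joint low/high grey-level zone-emphasis features,
#' and the zone-probability-weighted grey-level and zone-size variances.
#'
#' @inheritParams glcm_matrix
#' @return Named numeric vector of length 13.
#' @export
glszm_features <- function(q) {
  z <- glszm_zones(q)
  lev <- z[, 1]
  size <- z[, 2]
  nz <- nrow(z)
  np <- sum(q$mask)
  mu_l <- mean(lev)
  mu_s <- mean(size)
  out <- c(
    GLSZM_small_zone_emphasis = mean(1 / size^2),
    GLSZM_large_zone_emphasis = mean(size^2),
    GLSZM_grey_level_nonuniformity = sum(table(lev)^2) / nz,
    GLSZM_zone_size_nonuniformity = sum(table(size)^2) / nz,
    GLSZM_zone_percentage = nz / np,
    GLSZM_low_grey_level_zone_emphasis = mean(1 / lev^2),
    GLSZM_high_grey_level_zone_emphasis = mean(lev^2),
    GLSZM_small_zone_low_grey_level_emphasis = mean(1 / (size^2 * lev^2)),
    GLSZM_small_zone_high_grey_level_emphasis = mean(lev^2 / size^2),
    GLSZM_large_zone_low_grey_level_emphasis = mean(size^2 / lev^2),
    GLSZM_large_zone_high_grey_level_emphasis = mean(size^2 * lev^2),
    GLSZM_grey_level_variance = mean((lev - mu_l)^2),
    GLSZM_zone_size_variance = mean((size - mu_s)^2)
  )
  stopifnot(identical(names(out), feature_names_glszm()))
  out
}

#' The 5 neighbourhood grey-tone difference (NGLDM) features
#'
#' Amadasun-King coarseness, contrast, busyness, complexity and texture
#' strength from per-level accumulated absolute differences between each
#' in-mask voxel's level and the mean level of its in-mask 26-neighbourhood.
#' Coarseness and strength carry a `1e-12` additive guard in the denominator
#' so constant ROIs stay finite; contrast and busyness of a single-level ROI
#' are 0 by convention.
#'
#' @inheritParams glcm_matrix
#' @return Named numeric vector of length 5. If no in-mask voxel has an
#'   in-mask neighbour the vector is all-`NA` with attribute
#'   `degenerate = TRUE`.
#' @export
ngldm_features <- function(q) {
  check_quantized(q)
  st <- .ngtdm_stats_cpp(as.integer(q$levels), dim(q$levels), q$G)
  nm <- feature_names_ngldm()
  N <- sum(st$n)
  if (N == 0) {
    out <- setNames(rep(NA_real_, length(nm)), nm)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  eps <- 1e-12
  p <- st$n / N
  s <- st$s
  act <- which(p > 0)
  ngp <- length(act)
  i <- act
  pi_ <- p[act]
  si <- s[act]
  DI <- outer(i, i, "-")
  contrast <- if (ngp > 1) {
    (sum(outer(pi_, pi_) * DI^2) / (ngp * (ngp - 1))) * (sum(s) / N)
  } else 0
  bden <- sum(abs(outer(i * pi_, i * pi_, "-")))
  busyness <- if (bden > 0) sum(pi_ * si) / bden else 0
  PS <- outer(pi_ * si, pi_ * si, "+")
  PP <- outer(pi_, pi_, "+")
  complexity <- sum(abs(DI) * PS / PP) / N
  strength <- sum(PP * DI^2) / (sum(s) + eps)
  out <- c(
    NGLDM_coarseness = 1 / (sum(pi_ * si) + eps),
    NGLDM_contrast = contrast,
    NGLDM_busyness = busyness,
    NGLDM_complexity = complexity,
    NGLDM_texture_strength = strength
  )
  stopifnot(identical(names(out), nm))
  out
}
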
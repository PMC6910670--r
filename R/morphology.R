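#' The 6 morphological features of a binary mask
#'
#' Volume is voxel count times voxel volume. Surface area is measured on the
#' boundary mesh formed by the exposed faces of the voxelized region (every
#' mask-voxel face adjacent to background or to the grid border contributes
#' its physical face area); this mesh is exact for axis-aligned shapes.
#' Sphericity is \eqn{(36 \pi V^2)^{1/3} / A} and compactness
#' \eqn{36 \pi V^2 / A^3} (its cube), both 1 for a perfect sphere and
#' strictly below 1 for any voxelized region. The maximum 3D diameter is the
#' largest pairwise distance between boundary-voxel centers, in mm.
#'
#' @param mask logical/0-1 3D array.
#' @param spacing numeric length-3 voxel spacing in mm.
#' @return Named numeric vector of length 6: volume (mm^3), surface area
#'   (mm^2), surface-to-volume ratio (1/mm), sphericity, compactness and
#'   maximum 3D diameter (mm).
#' @export
morphological_features <- function(mask, spacing = c(1, 1, 1)) {
  mask <- array(as.logical(mask), dim = dim(mask))
  if (length(dim(mask)) != 3L) stop_deltarad("`mask` must be a 3D array")
  if (!any(mask)) stop_deltarad("mask is empty")
  spacing <- as.numeric(spacing)

  nvox <- sum(mask)
  vol <- nvox * prod(spacing)

  # pad with background so grid-border faces count as exposed
  d <- dim(mask)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  shift <- function(a, dx, dy, dz) {
    i <- seq_len(d[1]) + 1L + dx
    j <- seq_len(d[2]) + 1L + dy
    k <- seq_len(d[3]) + 1L + dz
    a[i, j, k, drop = FALSE]
  }
  face_area <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
                 spacing[1] * spacing[2])
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  area <- 0
  exposed <- array(FALSE, d)
  for (r in seq_len(nrow(offs))) {
    nb <- shift(pad, offs[r, 1], offs[r, 2], offs[r, 3])
    faces <- mask & !nb
    area <- area + sum(faces) * face_area[ceiling(r / 2)]
    exposed <- exposed | faces
  }

  # maximum diameter over boundary-voxel centers
  bidx <- which(exposed, arr.ind = TRUE)
  pts <- sweep(bidx - 1, 2, spacing, `*`)
  maxd <- 0
  if (nrow(pts) > 1) {
    # per-axis chunking keeps the pairwise distance matrix modest
    n <- nrow(pts)
    step <- 2000L
    for (s in seq(1, n, by = step)) {
      e <- min(s + step - 1L, n)
      dd <- outer(pts[s:e, 1], pts[, 1], `-`)^2 +
        outer(pts[s:e, 2], pts[, 2], `-`)^2 +
        outer(pts[s:e, 3], pts[, 3], `-`)^2
      maxd <- max(maxd, max(dd))
    }
    maxd <- sqrt(maxd)
  }

  sph <- (36 * pi * vol^2)^(1 / 3) / area
  out <- c(
    MORPH_volume = vol,
    MORPH_surface_area = area,
    MORPH_surface_to_volume_ratio = area / vol,
    MORPH_sphericity = sph,
    MORPH_compactness = 36 * pi * vol^2 / area^3,
    MORPH_max_diameter_3d = maxd
  )
  stopifnot(identical(names(out), feature_names_morph()))
  out
}

#' The 4 intensity-histogram features
#'
#' Population (n-denominator) moments of the raw, unquantized in-mask
#' intensities: mean, variance, skewness and excess kurtosis. Skewness and
#' kurtosis of a constant ROI are defined as 0.
#'
#' @param image an [image_volume] or 3D numeric array.
#' @param mask logical/0-1 array of the same dimensions.
#' @return Named numeric vector of length 4.
#' @export
histogram_features <- function(image, mask) {
  vox <- as_volume_array(image)
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!identical(dim(vox), dim(mask)))
    stop_deltarad("image and mask dimensions differ")
  if (!any(mask)) stop_deltarad("mask is empty")
  x <- vox[mask]
  n <- length(x)
  m <- mean(x)
  m2 <- sum((x - m)^2) / n
  if (m2 <= 0) {
    skew <- 0
    kurt <- 0
  } else {
    skew <- (sum((x - m)^3) / n) / m2^1.5
    kurt <- (sum((x - m)^4) / n) / m2^2 - 3
  }
  out <- c(HIST_mean = m, HIST_variance = m2, HIST_skewness = skew,
           HIST_kurtosis = kurt)
  stopifnot(identical(names(out), feature_names_hist()))
  out
}
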
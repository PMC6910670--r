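#' Construct an image volume
#'
#' Light container for one 3D scalar grid plus acquisition metadata.
#'
#' @param voxels 3D numeric array of intensities (arbitrary units).
#' @param spacing numeric length-3 voxel spacing in mm.
#' @param modality modality tag, e.g. `"T1"` or `"T2FLAIR"`.
#' @param timepoint timepoint tag, e.g. `"pre"`, `"post1"`, `"post2"`.
#' @param patient_id patient identifier.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing = c(1, 1, 1), modality = "T1",
                         timepoint = "pre", patient_id = "P01") {
  if (length(dim(voxels)) != 3L)
    stop_deltarad("`voxels` must be a 3D array")
  if (!all(is.finite(voxels)))
    stop_deltarad("all intensities must be finite")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop_deltarad("`spacing` must be 3 positive values (mm)")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 modality = modality, timepoint = timepoint,
                 patient_id = patient_id),
            class = "image_volume")
}

as_volume_array <- function(image) {
  if (inherits(image, "image_volume")) image$voxels else image
}

#' Quantize a region of interest to G grey levels
#'
#' Re-bins the in-mask intensities of a volume into `G` equal-width bins
#' between the ROI minimum and maximum. The minimum maps to level 1 and the
#' maximum to level `G` (right-closed last bin, so the top bin is never
#' empty). A constant ROI maps every voxel to level 1 and is flagged
#' degenerate. The result is cropped to the mask bounding box; voxels outside
#' the mask carry level 0.
#'
#' @param image an [image_volume] or 3D numeric array.
#' @param mask logical/0-1 array of the same dimensions.
#' @param G number of grey levels (default 64).
#' @return An object of class `quantized_roi` with elements `levels`
#'   (integer array over the bounding box, 1..G in-mask, 0 outside), `mask`
#'   (logical array), `G`, `spacing` and `degenerate` (constant-ROI flag).
#' @export
quantize_roi <- function(image, mask, G = 64L) {
  vox <- as_volume_array(image)
  spacing <- if (inherits(image, "image_volume")) image$spacing else c(1, 1, 1)
  G <- as.integer(G)
  if (G < 2L) stop_deltarad("`G` must be at least 2")
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!identical(dim(vox), dim(mask)))
    stop_deltarad("image and mask dimensions differ")
  if (!any(mask)) stop_deltarad("mask is empty")

  bb <- lapply(1:3, function(ax) {
    keep <- apply(mask, ax, any)
    range(which(keep))
  })
  crop <- function(a) a[bb[[1]][1]:bb[[1]][2], bb[[2]][1]:bb[[2]][2],
                        bb[[3]][1]:bb[[3]][2], drop = FALSE]
  vox <- crop(vox)
  mask <- crop(mask)

  vals <- vox[mask]
  lo <- min(vals); hi <- max(vals)
  degenerate <- (hi - lo) <= 0
  levels <- array(0L, dim = dim(vox))
  if (degenerate) {
    levels[mask] <- 1L
  } else {
    lv <- floor((vox[mask] - lo) / (hi - lo) * G) + 1L
    levels[mask] <- as.integer(pmin(lv, G))
  }
  structure(list(levels = levels, mask = mask, G = G,
                 spacing = as.numeric(spacing), degenerate = degenerate),
            class = "quantized_roi")
}

check_quantized <- function(q) {
  if (!inherits(q, "quantized_roi"))
    stop_deltarad("expected a `quantized_roi` object")
  q
}

# the 13 unique distance-1 3D directions (one per antipodal pair)
unique_directions_3d <- function() {
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- d[rowSums(abs(d)) > 0, , drop = FALSE]
  keep <- apply(d, 1, function(v) {
    nz <- v[v != 0]
    nz[1] > 0
  })
  m <- d[keep, , drop = FALSE]
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  m
}
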
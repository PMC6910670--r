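feature_names_glcom <- function() {
  paste0("GLCOM_", c(
    "energy", "entropy", "contrast", "dissimilarity", "homogeneity",
    "inverse_difference_moment", "inverse_difference_moment_normalized",
    "inverse_difference_normalized", "correlation", "autocorrelation",
    "cluster_tendency", "cluster_shade", "cluster_prominence",
    "maximum_probability", "joint_average", "joint_variance",
    "sum_average", "sum_variance", "sum_entropy",
    "difference_average", "difference_variance", "difference_entropy"))
}

feature_names_glrlm <- function() {
  paste0("GLRLM_", c(
    "short_run_emphasis", "long_run_emphasis", "grey_level_nonuniformity",
    "run_length_nonuniformity", "run_percentage",
    "low_grey_level_run_emphasis", "high_grey_level_run_emphasis",
    "short_run_low_grey_level_emphasis",
    "short_run_high_grey_level_emphasis",
    "long_run_low_grey_level_emphasis",
    "long_run_high_grey_level_emphasis"))
}

feature_names_glszm <- function() {
  paste0("GLSZM_", c(
    "small_zone_emphasis", "large_zone_emphasis",
    "grey_level_nonuniformity", "zone_size_nonuniformity",
    "zone_percentage", "low_grey_level_zone_emphasis",
    "high_grey_level_zone_emphasis",
    "small_zone_low_grey_level_emphasis",
    "small_zone_high_grey_level_emphasis",
    "large_zone_low_grey_level_emphasis",
    "large_zone_high_grey_level_emphasis",
    "grey_level_variance", "zone_size_variance"))
}

feature_names_ngldm <- function() {
  paste0("NGLDM_", c("coarseness", "contrast", "busyness", "complexity",
                     "texture_strength"))
}

feature_names_morph <- function() {
  paste0("MORPH_", c("volume", "surface_area", "surface_to_volume_ratio",
                     "sphericity", "compactness", "max_diameter_3d"))
}

feature_names_hist <- function() {
  paste0("HIST_", c("mean", "variance", "skewness", "kurtosis"))
}

#' The radiomic feature registry
#'
#' Canonical names, family membership and ordering of the 61 features
#' produced by [extract_all()]: 22 co-occurrence (GLCOM), 11 run-length
#' (GLRLM), 13 size-zone (GLSZM) and 5 neighbourhood grey-tone difference
#' (NGLDM) texture features, 6 morphological features and 4
#' intensity-histogram features. The family cardinalities
#' (22 + 11 + 13 + 5 + 6 + 4 = 61) are asserted on every call.
#'
#' @return A data frame with columns `name` and `family`, 61 rows, in the
#'   fixed extraction order.
#' @export
feature_registry <- function() {
  fams <- list(GLCOM = feature_names_glcom(),
               GLRLM = feature_names_glrlm(),
               GLSZM = feature_names_glszm(),
               NGLDM = feature_names_ngldm(),
               MORPH = feature_names_morph(),
               HIST = feature_names_hist())
  counts <- lengths(fams)
  stopifnot(identical(unname(counts),
                      c(22L, 11L, 13L, 5L, 6L, 4L)),
            sum(counts) == 61L)
  data.frame(name = unlist(fams, use.names = FALSE),
             family = rep(names(fams), counts),
             stringsAsFactors = FALSE)
}

#' Extract the full 61-feature radiomic vector
#'
#' Quantizes the ROI to `G` grey levels and concatenates the six feature
#' families in registry order. Deterministic, and invariant to voxel values
#' outside the mask.
#'
#' @param image an [image_volume] or 3D numeric array.
#' @param mask logical/0-1 array of the same dimensions.
#' @param G grey-level count for texture quantization (default 64).
#' @param spacing voxel spacing in mm; taken from `image` when it is an
#'   [image_volume].
#' @return An object of class `feature_vector`: a named numeric vector of
#'   length 61 with attributes `modality`, `timepoint`, `patient_id` and
#'   `degenerate` (TRUE when a texture family could not be computed and its
#'   entries are `NA`).
#' @export
extract_all <- function(image, mask, G = 64L, spacing = NULL) {
  if (inherits(image, "image_volume")) {
    spacing <- image$spacing
    meta <- image[c("modality", "timepoint", "patient_id")]
  } else {
    spacing <- spacing %||% c(1, 1, 1)
    meta <- list(modality = NA_character_, timepoint = NA_character_,
                 patient_id = NA_character_)
  }
  q <- quantize_roi(image, mask, G)
  parts <- list(glcom_features(q), glrlm_features(q), glszm_features(q),
                ngldm_features(q),
                morphological_features(mask, spacing),
                histogram_features(image, mask))
  degenerate <- any(vapply(parts, function(p)
    isTRUE(attr(p, "degenerate")), logical(1)))
  out <- unlist(lapply(parts, unclass))
  stopifnot(identical(names(out), feature_registry()$name))
  structure(out, class = "feature_vector", modality = meta$modality,
            timepoint = meta$timepoint, patient_id = meta$patient_id,
            degenerate = degenerate)
}

#' Extract features for every volume of a cohort
#'
#' Runs [extract_all()] on each patient's six volumes (2 modalities x 3
#' time points) against the patient's shared GTV mask.
#'
#' @param cohort list of patient image sets from [generate_cohort()] (or
#'   [read_cohort()]).
#' @param G grey-level count (default 64).
#' @return A data frame with columns `patient_id`, `modality`, `timepoint`
#'   and the 61 feature columns.
#' @export
extract_cohort <- function(cohort, G = 64L) {
  rows <- list()
  for (pat in cohort) {
    for (v in pat$volumes) {
      fv <- extract_all(v, pat$gtv_mask, G = G)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = v$patient_id, modality = v$modality,
        timepoint = v$timepoint, t(as.numeric(fv)),
        stringsAsFactors = FALSE)
      names(rows[[length(rows)]])[-(1:3)] <- names(fv)
    }
  }
  do.call(rbind, rows)
}
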
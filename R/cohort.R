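#' Configuration for the synthetic multi-timepoint cohort
#'
#' Defines the simulated study conditions: a small cohort (default 12
#' patients) of co-registered two-modality (T1, T2-FLAIR) 3D volumes at
#' three time points (pre-treatment, one-week and two-month post-treatment)
#' sharing one GTV mask per patient, with dichotomized survival (class 0:
#' OS < 12 months, class 1: OS >= 12 months).
#'
#' Pre-treatment volumes are label-independent textured random fields
#' (smoothed Gaussian noise around a per-patient, per-modality base
#' intensity). Post-treatment volumes add smooth acquisition noise
#' everywhere and, for class-1 patients only, a high-frequency (voxel-wise
#' white) intensity perturbation of standard deviation `effect_size` inside
#' the GTV of the T1 volumes. This plants a post-treatment texture change -
#' a rise in high-frequency co-occurrence statistics, most directly GLCOM
#' contrast - that is associated with the survival class, while
#' pre-treatment images carry no class information by construction.
#' `effect_size = 0` disables the perturbation entirely, making every image
#' statistically independent of the class label.
#'
#' @param n_patients number of patients (>= 3, default 12).
#' @param grid_shape integer length-3 grid dimensions (default 32^3).
#' @param voxel_spacing numeric length-3 spacing in mm (default 1 mm
#'   isotropic).
#' @param corr_length_vox correlation length (Gaussian smoothing sigma, in
#'   voxels) of the background texture field (default 2).
#' @param texture_amplitude standard deviation of the background texture
#'   field in intensity units (default 10).
#' @param effect_size standard deviation of the class-1 post-treatment
#'   in-mask perturbation, in intensity units (>= 0, default 2).
#' @param noise_sd standard deviation of the smooth scan-to-scan noise added
#'   to every post-treatment volume (default 1).
#' @param class_balance fraction of patients in class 1 (default 0.5,
#'   i.e. 6/12 long survivors).
#' @param survival_range_months overall-survival range; class 0 is drawn
#'   uniformly on `[min, 12)`, class 1 on `[12, max]` (default 5.3-29.4).
#' @param censoring_fraction fraction of patients whose event indicator is
#'   set to 0 (default 0, all deaths observed).
#' @param mask_radius_vox nominal GTV ellipsoid radius in voxels (default
#'   `min(grid_shape) / 4.5`); each patient's three semi-axes are drawn
#'   uniformly within +/-15% of it, and the smallest admissible mask must
#'   still contain at least 100 voxels.
#' @param seed integer RNG seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 12L,
                          grid_shape = c(32L, 32L, 32L),
                          voxel_spacing = c(1, 1, 1),
                          corr_length_vox = 2,
                          texture_amplitude = 10,
                          effect_size = 2,
                          noise_sd = 1,
                          class_balance = 0.5,
                          survival_range_months = c(5.3, 29.4),
                          censoring_fraction = 0,
                          mask_radius_vox = NULL,
                          seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              grid_shape = as.integer(grid_shape),
              voxel_spacing = as.numeric(voxel_spacing),
              corr_length_vox = corr_length_vox,
              texture_amplitude = texture_amplitude,
              effect_size = effect_size,
              noise_sd = noise_sd,
              class_balance = class_balance,
              survival_range_months = as.numeric(survival_range_months),
              censoring_fraction = censoring_fraction,
              mask_radius_vox = mask_radius_vox %||%
                (min(grid_shape) / 4.5),
              seed = as.integer(seed))
  if (cfg$n_patients < 3L) stop_deltarad("need at least 3 patients")
  if (cfg$effect_size < 0) stop_deltarad("`effect_size` must be >= 0")
  if (cfg$class_balance <= 0 || cfg$class_balance >= 1)
    stop_deltarad("`class_balance` must be in (0, 1)")
  if (cfg$censoring_fraction < 0 || cfg$censoring_fraction >= 1)
    stop_deltarad("`censoring_fraction` must be in [0, 1)")
  if (cfg$survival_range_months[1] >= 12 ||
      cfg$survival_range_months[2] < 12)
    stop_deltarad("`survival_range_months` must straddle 12 months")
  class(cfg) <- "cohort_config"
  cfg
}

# separable Gaussian smoothing with edge renormalization; sigma in voxels
smooth_field <- function(a, sigma) {
  d <- dim(a)
  half <- max(1L, ceiling(3 * sigma))
  kern <- exp(-0.5 * ((-half:half) / sigma)^2)
  for (ax in 1:3) {
    n <- d[ax]
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- pmax(1L, i - half):pmin(n, i + half)
      w <- kern[j - i + half + 1L]
      K[i, j] <- w / sum(w)
    }
    a <- aperm(a, c(ax, setdiff(1:3, ax)))
    dm <- dim(a)
    a <- array(K %*% matrix(a, dm[1]), dm)
    a <- aperm(a, order(c(ax, setdiff(1:3, ax))))
  }
  a
}

ellipsoid_mask <- function(grid_shape, radii) {
  radii <- rep_len(radii, 3)
  ctr <- (grid_shape + 1) / 2
  ax <- lapply(1:3, function(k) (seq_len(grid_shape[k]) - ctr[k]) /
                 radii[k])
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  r2 <= 1
}

#' Generate a synthetic multi-timepoint imaging cohort
#'
#' Simulates the cohort described in [cohort_config()]: for each patient,
#' six volumes (2 modalities x 3 time points) on a shared grid with one GTV
#' mask, plus a survival record whose class label is 0 iff overall survival
#' is below 12 months. Deterministic given `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return A list with elements `patients` (list of patient image sets, each
#'   with `patient_id`, `volumes` (named list of six [image_volume]s) and
#'   `gtv_mask`), `survival` (data frame with `patient_id`, `os_months`,
#'   `event`, `class_label`), `planted_effect` (description of where the
#'   class-linked perturbation acts) and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config"))
    stop_deltarad("`config` must be a cohort_config")
  if (sum(ellipsoid_mask(config$grid_shape,
                         0.85 * config$mask_radius_vox)) < 100)
    stop_deltarad("GTV mask has fewer than 100 voxels; enlarge the grid ",
                  "or the mask radius")
  n <- config$n_patients
  out <- with_seed(config$seed, {
    n1 <- round(n * config$class_balance)
    cls <- sample(rep(c(1L, 0L), c(n1, n - n1)))
    rng <- config$survival_range_months
    os <- ifelse(cls == 1L, runif(n, 12, rng[2]), runif(n, rng[1], 12))
    event <- rep(1L, n)
    ncens <- floor(config$censoring_fraction * n)
    if (ncens > 0) event[sample.int(n, ncens)] <- 0L
    ids <- sprintf("P%02d", seq_len(n))
    survival <- data.frame(patient_id = ids, os_months = os, event = event,
                           class_label = cls, stringsAsFactors = FALSE)

    patients <- vector("list", n)
    base_mean <- c(T1 = 100, T2FLAIR = 140)
    for (p in seq_len(n)) {
      # per-patient tumor geometry: random semi-axes around the nominal
      # radius, one mask shared by all six volumes
      mask <- ellipsoid_mask(config$grid_shape,
                             config$mask_radius_vox * runif(3, 0.85, 1.15))
      nmask <- sum(mask)
      vols <- list()
      for (mod in c("T1", "T2FLAIR")) {
        base <- rnorm(1, base_mean[[mod]], 10)
        f <- smooth_field(array(rnorm(prod(config$grid_shape)),
                                config$grid_shape),
                          config$corr_length_vox)
        f <- f / sd(as.vector(f)) * config$texture_amplitude
        pre <- base + f
        for (tp in c("pre", "post1", "post2")) {
          v <- pre
          if (tp != "pre") {
            g <- smooth_field(array(rnorm(prod(config$grid_shape)),
                                    config$grid_shape),
                              config$corr_length_vox)
            v <- v + config$noise_sd * g / sd(as.vector(g))
            # the perturbation field is drawn for every T1 post volume so
            # that cohorts generated from the same seed are voxel-identical
            # across effect sizes except for the planted signal itself
            if (mod == "T1") {
              pert <- rnorm(nmask)
              if (cls[p] == 1L)
                v[mask] <- v[mask] + config$effect_size * pert
            }
          }
          vols[[paste(mod, tp, sep = "_")]] <- image_volume(
            v, spacing = config$voxel_spacing, modality = mod,
            timepoint = tp, patient_id = ids[p])
        }
      }
      patients[[p]] <- list(patient_id = ids[p], volumes = vols,
                            gtv_mask = mask)
    }
    list(patients = patients, survival = survival)
  })
  out$planted_effect <- list(
    modality = "T1", timepoints = c("post1", "post2"),
    description = paste("class-1 in-GTV high-frequency intensity",
                        "perturbation; raises the T1 delta values of the",
                        "high-frequency texture family (GLCOM",
                        "contrast-type, NGLDM, run-length and zone-size",
                        "statistics)"))
  out$config <- config
  out
}

#' Write a cohort to disk as NIfTI + CSV
#'
#' Volumes are written as float32 NIfTI (one file per patient, modality and
#' time point), masks as uint8 NIfTI, survival as CSV, and a JSON manifest
#' listing every file is returned and saved alongside.
#'
#' @param cohort result of [generate_cohort()].
#' @param out_dir output directory (created if needed).
#' @return The manifest, invisibly (list with `patients`, `survival_csv`,
#'   `n_patients`).
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop_deltarad("cannot create ", out_dir)
  manifest <- list(n_patients = length(cohort$patients),
                   survival_csv = "survival.csv", patients = list())
  for (pat in cohort$patients) {
    files <- list()
    for (v in pat$volumes) {
      fn <- sprintf("%s_%s_%s.nii.gz", pat$patient_id, v$modality,
                    v$timepoint)
      RNifti::writeNifti(
        RNifti::asNifti(v$voxels, datatype = "float"),
        file.path(out_dir, fn))
      files[[paste(v$modality, v$timepoint, sep = "_")]] <- fn
    }
    mfn <- sprintf("%s_mask.nii.gz", pat$patient_id)
    RNifti::writeNifti(
      RNifti::asNifti(array(as.integer(pat$gtv_mask),
                            dim = dim(pat$gtv_mask)),
                      datatype = "uint8"),
      file.path(out_dir, mfn))
    files[["mask"]] <- mfn
    manifest$patients[[pat$patient_id]] <- files
  }
  write.csv(cohort$survival, file.path(out_dir, "survival.csv"),
            row.names = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `manifest.json`.
#' @return A cohort list with `patients` and `survival`, as in
#'   [generate_cohort()].
#' @export
read_cohort <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"))
  survival <- read.csv(file.path(dir, mf$survival_csv),
                       stringsAsFactors = FALSE)
  patients <- lapply(names(mf$patients), function(pid) {
    files <- mf$patients[[pid]]
    mask_img <- RNifti::readNifti(file.path(dir, files$mask))
    mask <- array(as.logical(mask_img > 0), dim = dim(mask_img))
    vols <- list()
    for (key in setdiff(names(files), "mask")) {
      parts <- strsplit(key, "_", fixed = TRUE)[[1]]
      img <- RNifti::readNifti(file.path(dir, files[[key]]))
      vols[[key]] <- image_volume(array(as.numeric(img), dim = dim(img)),
                                  spacing = RNifti::pixdim(img),
                                  modality = parts[1], timepoint = parts[2],
                                  patient_id = pid)
    }
    list(patient_id = pid, volumes = vols, gtv_mask = mask)
  })
  list(patients = patients, survival = survival)
}
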
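#' Configuration of the synthetic two-class cohort
#'
#' Defines the study conditions the generator emulates: a 54-lesion cohort
#' (25 BRAF-positive, 29 BRAF-negative), class-dependent ages (55 +- 14 vs
#' 64.4 +- 12.3 years), class-dependent lesion texture heterogeneity (the
#' BRAF-negative class has the shorter texture correlation length, i.e. the
#' more heterogeneous signal), and class-dependent location priors over the 16
#' atlas regions (positive lesions favour the right limbic and left parietal
#' regions, negative lesions the left frontal region).
#'
#' Lesion intensity texture is a Gaussian random field with a uniformized
#' marginal: seeded white noise smoothed with a per-class correlation length,
#' rank-mapped within the lesion to a uniform marginal of per-class standard
#' deviation (a copula construction that makes class differences purely
#' spatial, independent of marginal tail effects), and added to a constant
#' lesion baseline. The background holds a homogeneous reference block
#' standing in for normal-appearing white matter. Default lesion radii
#' (7-12 voxels, i.e. 1.4-2.4 cm diameter at 1 mm spacing) match surgically
#' resected metastases and keep every co-occurrence offset sampled at the
#' default displacement of 8.
#'
#' @param n_positive,n_negative Lesion counts per class.
#' @param grid_shape Volume dimensions in voxels.
#' @param spacing Voxel size (mm).
#' @param age_mean,age_sd Named per-class (`positive`, `negative`) normal age
#'   parameters, years.
#' @param gender_p_female Per-class probability that a subject is female
#'   (gender code 1 = female, 0 = male).
#' @param lesion_radius_range Uniform range (voxels) for each ellipsoid
#'   semi-axis.
#' @param lesion_roughness Amplitude of smooth surface perturbation of the
#'   ellipsoid level set; 0 keeps lesions exactly ellipsoidal.
#' @param texture_correlation_length Per-class Gaussian-field smoothing sigma
#'   in voxels; smaller = more heterogeneous texture.
#' @param texture_noise_sd Per-class marginal SD of the texture field
#'   (raw intensity units).
#' @param lesion_baseline,background_level,background_noise_sd Raw intensity
#'   levels of the enhancing lesion and the surrounding background.
#' @param reference_level,reference_noise_sd Intensity of the homogeneous
#'   white-matter reference block.
#' @param location_prior 2 x 16 matrix (rows `positive`, `negative`) of
#'   nonnegative region weights; `NULL` uses the default class-skewed prior.
#' @param two_lesion_patient If `TRUE`, the last two negative lesions belong
#'   to one patient (exercises patient-grouped folding).
#' @param seed Master seed; all per-subject randomness derives from it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_positive = 25L,
                          n_negative = 29L,
                          grid_shape = c(64L, 64L, 64L),
                          spacing = c(1, 1, 1),
                          age_mean = c(positive = 55, negative = 64.4),
                          age_sd = c(positive = 14, negative = 12.3),
                          gender_p_female = c(positive = 9 / 25, negative = 12 / 29),
                          lesion_radius_range = c(7, 12),
                          lesion_roughness = 0,
                          texture_correlation_length = c(positive = 6, negative = 1.5),
                          texture_noise_sd = c(positive = 120, negative = 120),
                          lesion_baseline = 600,
                          background_level = 150,
                          background_noise_sd = 10,
                          reference_level = 400,
                          reference_noise_sd = 4,
                          location_prior = NULL,
                          two_lesion_patient = FALSE,
                          seed = 1L) {
  if (is.null(location_prior)) {
    location_prior <- default_location_prior()
  }
  cfg <- list(
    n_positive = as.integer(n_positive), n_negative = as.integer(n_negative),
    grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
    age_mean = age_mean, age_sd = age_sd, gender_p_female = gender_p_female,
    lesion_radius_range = as.numeric(lesion_radius_range),
    lesion_roughness = lesion_roughness,
    texture_correlation_length = texture_correlation_length,
    texture_noise_sd = texture_noise_sd,
    lesion_baseline = lesion_baseline,
    background_level = background_level,
    background_noise_sd = background_noise_sd,
    reference_level = reference_level,
    reference_noise_sd = reference_noise_sd,
    location_prior = location_prior,
    two_lesion_patient = isTRUE(two_lesion_patient),
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_positive < 1L || cfg$n_negative < 1L) {
    abort("Class counts must be >= 1.", class = "radbiopsy_bad_config")
  }
  if (any(cfg$texture_correlation_length <= 0)) {
    abort("Texture correlation lengths must be > 0.",
          class = "radbiopsy_bad_config")
  }
  lp <- cfg$location_prior
  if (!is.matrix(lp) || nrow(lp) != 2L || ncol(lp) != 16L ||
      any(lp < 0) || any(rowSums(lp) <= 0)) {
    abort("location_prior must be a 2 x 16 nonnegative matrix with positive row sums.",
          class = "radbiopsy_bad_config")
  }
  for (nm in c("age_mean", "age_sd", "gender_p_female",
               "texture_correlation_length", "texture_noise_sd")) {
    if (!all(c("positive", "negative") %in% names(cfg[[nm]]))) {
      abort(paste0("`", nm, "` needs named 'positive' and 'negative' entries."),
            class = "radbiopsy_bad_config")
    }
  }
  invisible(cfg)
}

#' Default class-skewed location prior
#'
#' Uniform weight 1 on every region, with weight 3 on right limbic and left
#' parietal for the positive class and on left frontal for the negative class
#' (the location asymmetries the classifier is meant to pick up).
#'
#' @return 2 x 16 matrix, rows `positive` / `negative`, columns the atlas
#'   regions.
#' @export
default_location_prior <- function() {
  rn <- atlas_region_names()
  lp <- matrix(1, nrow = 2, ncol = 16, dimnames = list(c("positive", "negative"), rn))
  lp["positive", c("limbic_right", "parietal_left")] <- 3
  lp["negative", "frontal_left"] <- 3
  lp
}

#' A null configuration with identical class parameters
#'
#' Both classes share ages, gender rates, location priors and texture
#' parameters, so any downstream class separation is spurious; used to
#' calibrate the pipeline (cross-validated AUC should concentrate near 0.5).
#'
#' @param ... Overrides passed to [cohort_config()].
#' @return A `cohort_config`.
#' @export
null_cohort_config <- function(...) {
  rn <- atlas_region_names()
  lp <- matrix(1, 2, 16, dimnames = list(c("positive", "negative"), rn))
  cohort_config(
    age_mean = c(positive = 60, negative = 60),
    age_sd = c(positive = 13, negative = 13),
    gender_p_female = c(positive = 21 / 54, negative = 21 / 54),
    texture_correlation_length = c(positive = 2, negative = 2),
    texture_noise_sd = c(positive = 120, negative = 120),
    location_prior = lp,
    ...
  )
}

#' A strong-texture-separation configuration
#'
#' The parameter-recovery condition: classes differ sharply in texture
#' correlation length (8 voxels for the positive class — smooth at the
#' co-occurrence displacement scale — vs 1 for the negative), all other
#' parameters at their defaults. Under this
#' configuration the cross-validated classifier should recover the class
#' structure with high AUC, and the negative class remains the more
#' heterogeneous one.
#'
#' @param ... Overrides passed to [cohort_config()].
#' @return A `cohort_config`.
#' @export
strong_separation_config <- function(...) {
  cohort_config(texture_correlation_length = c(positive = 8, negative = 1),
                ...)
}

#' Generate one synthetic subject
#'
#' Draws a lesion region from the class location prior, places an ellipsoidal
#' enhancing lesion there, fills it with the class's Gaussian-random-field
#' texture, adds a homogeneous reference block and noisy background, and draws
#' age/gender from the class demographics. Identical `(config, braf_status,
#' seed)` give a bit-identical case.
#'
#' @param config A [cohort_config()].
#' @param braf_status `"positive"` or `"negative"`.
#' @param seed Integer seed for this subject.
#' @param atlas Optional precomputed [build_grid_atlas()] for `config`'s grid
#'   (rebuilt, deterministically, when `NULL`).
#' @return A `subject_case`: `volume`, `lesion`, `reference`, `atlas`, `age`,
#'   `gender`, `braf_status`, `seed_used`.
#' @export
generate_subject <- function(config, braf_status, seed, atlas = NULL) {
  validate_cohort_config(config)
  braf_status <- match.arg(braf_status, c("positive", "negative"))
  if (is.null(atlas)) atlas <- build_grid_atlas(config$grid_shape, config$spacing)
  d <- config$grid_shape
  rmax <- max(config$lesion_radius_range)
  if (any(2 * ceiling(rmax) + 4 > d)) {
    abort("Lesion cannot fit in the grid: radius range too large for grid_shape.",
          class = "radbiopsy_lesion_too_big")
  }
  with_rng_seed(seed, {
    region <- sample.int(16L, 1L, prob = config$location_prior[braf_status, ])
    radii <- runif(3, config$lesion_radius_range[1], config$lesion_radius_range[2])
    box <- atlas_region_box(atlas, region)
    center <- vapply(1:3, function(a) {
      lo <- max(box[[a]][1], ceiling(radii[a]) + 2)
      hi <- min(box[[a]][2], d[a] - ceiling(radii[a]) - 1)
      if (lo > hi) (box[[a]][1] + box[[a]][2]) / 2 else runif(1, lo, hi)
    }, numeric(1))
    center <- pmin(pmax(center, ceiling(radii) + 2), d - ceiling(radii) - 1)

    # ellipsoid (optionally roughened) inside its bounding box
    pad <- 3L
    lo <- pmax(1L, floor(center - radii) - pad)
    hi <- pmin(d, ceiling(center + radii) + pad)
    bd <- hi - lo + 1L
    ex <- (seq.int(lo[1], hi[1]) - center[1]) / radii[1]
    ey <- (seq.int(lo[2], hi[2]) - center[2]) / radii[2]
    ez <- (seq.int(lo[3], hi[3]) - center[3]) / radii[3]
    level <- outer(outer(ex^2, ey^2, `+`), ez^2, `+`)
    if (config$lesion_roughness > 0) {
      pert <- smooth_gaussian3(array(rnorm(prod(bd)), dim = bd), 2)
      pert <- pert / max(sd(pert), 1e-12)
      level <- level + config$lesion_roughness * pert
    }
    inside <- level <= 1

    lesion <- array(FALSE, dim = d)
    lesion[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- inside

    # homogeneous reference block in the unlabeled corner, disjoint from lesion
    ref <- array(FALSE, dim = d)
    rb <- 3:6
    ref[rb, rb, rb] <- TRUE
    ref <- ref & !lesion

    vol <- array(config$background_level +
                   config$background_noise_sd * rnorm(prod(d)), dim = d)
    vol[ref] <- config$reference_level +
      config$reference_noise_sd * rnorm(sum(ref))

    # Texture: Gaussian random field restricted to the lesion bounding box,
    # then rank-uniformized within the lesion (copula construction). The
    # monotone marginal map leaves the field's spatial dependence in place
    # but gives every class the identical uniform marginal, so co-occurrence
    # differences between classes reflect spatial correlation structure
    # only, not the sample-size-dependent tails of a Gaussian marginal.
    corr <- config$texture_correlation_length[braf_status]
    noise_sd <- config$texture_noise_sd[braf_status]
    field <- smooth_gaussian3(array(rnorm(prod(bd)), dim = bd), corr)
    fl <- field[inside]
    u <- (rank(fl, ties.method = "average") - 0.5) / length(fl)
    sub <- vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    sub[inside] <- config$lesion_baseline + noise_sd * sqrt(12) * (u - 0.5)
    vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub

    age <- rnorm(1, config$age_mean[braf_status], config$age_sd[braf_status])
    gender <- rbinom(1, 1, config$gender_p_female[braf_status])

    structure(
      list(volume = image_volume(vol, config$spacing),
           lesion = image_volume(lesion, config$spacing),
           reference = image_volume(ref, config$spacing),
           atlas = atlas,
           age = age, gender = gender,
           braf_status = braf_status, seed_used = as.integer(seed)),
      class = "subject_case"
    )
  })
}

#' Generate a full synthetic cohort
#'
#' `n_positive + n_negative` subject cases with per-case seeds derived
#' deterministically from the master seed, plus a manifest tibble.
#'
#' @param config A [cohort_config()].
#' @return A `synthetic_cohort`: list with `cases` (list of `subject_case`)
#'   and `manifest` (tibble: subject_id, lesion_id, age, gender, braf_status,
#'   seed).
#' @examples
#' \donttest{
#' coh <- generate_cohort(cohort_config(n_positive = 2, n_negative = 2,
#'                                      grid_shape = c(32, 32, 32),
#'                                      lesion_radius_range = c(4, 6)))
#' coh$manifest
#' }
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  atlas <- build_grid_atlas(config$grid_shape, config$spacing)
  status <- rep(c("positive", "negative"), c(config$n_positive, config$n_negative))
  n <- length(status)
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    cases[[i]] <- generate_subject(config, status[i],
                                   seed = derive_seed(config$seed, i),
                                   atlas = atlas)
  }
  subject_id <- sprintf("sub%03d", seq_len(n))
  lesion_id <- sprintf("les%03d", seq_len(n))
  if (config$two_lesion_patient && config$n_negative >= 2L) {
    # last two negative lesions belong to one patient
    subject_id[n] <- subject_id[n - 1L]
    cases[[n]]$age <- cases[[n - 1L]]$age
    cases[[n]]$gender <- cases[[n - 1L]]$gender
  }
  manifest <- tibble(
    subject_id = subject_id,
    lesion_id = lesion_id,
    age = vapply(cases, `[[`, numeric(1), "age"),
    gender = vapply(cases, `[[`, numeric(1), "gender"),
    braf_status = status,
    seed = vapply(cases, `[[`, integer(1), "seed_used")
  )
  structure(list(cases = cases, manifest = manifest, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", length(x$cases), " lesions (",
      sum(x$manifest$braf_status == "positive"), " positive, ",
      sum(x$manifest$braf_status == "negative"), " negative), grid ",
      paste(x$config$grid_shape, collapse = "x"), "\n", sep = "")
  invisible(x)
}

#' Write a cohort to NIfTI + CSV on disk
#'
#' Writes per-lesion `*_t1c.nii.gz`, `*_lesion.nii.gz`, `*_ref.nii.gz`, one
#' shared `atlas.nii.gz`, and `manifest.csv` with file paths and covariates —
#' the same layout [read_cohort()] ingests.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  atlas_path <- file.path(dir, "atlas.nii.gz")
  atl <- cohort$cases[[1]]$atlas
  write_volume(image_volume(array(as.numeric(atl$labels), dim = atl$shape),
                            atl$spacing), atlas_path)
  man <- cohort$manifest
  man$volume_path <- file.path(dir, paste0(man$lesion_id, "_t1c.nii.gz"))
  man$lesion_path <- file.path(dir, paste0(man$lesion_id, "_lesion.nii.gz"))
  man$reference_path <- file.path(dir, paste0(man$lesion_id, "_ref.nii.gz"))
  man$atlas_path <- atlas_path
  for (i in seq_len(nrow(man))) {
    cs <- cohort$cases[[i]]
    write_volume(cs$volume, man$volume_path[i])
    write_volume(cs$lesion, man$lesion_path[i])
    write_volume(cs$reference, man$reference_path[i])
  }
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(as.data.frame(man), path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort from a manifest written by [write_cohort()]
#'
#' @param manifest_path Path to `manifest.csv` (or a directory containing it).
#' @return A `synthetic_cohort`-shaped list with `cases` and `manifest`.
#' @export
read_cohort <- function(manifest_path) {
  if (dir.exists(manifest_path)) {
    manifest_path <- file.path(manifest_path, "manifest.csv")
  }
  if (!file.exists(manifest_path)) {
    abort(paste0("Manifest not found: ", manifest_path),
          class = "radbiopsy_missing_file")
  }
  man <- as_tibble(utils::read.csv(manifest_path))
  need <- c("subject_id", "lesion_id", "age", "gender", "braf_status",
            "volume_path", "lesion_path", "reference_path", "atlas_path")
  missing_cols <- setdiff(need, names(man))
  if (length(missing_cols) > 0) {
    abort(paste0("Manifest lacks column(s): ", paste(missing_cols, collapse = ", ")),
          class = "radbiopsy_bad_manifest")
  }
  if (anyDuplicated(man[c("subject_id", "lesion_id")])) {
    abort("Manifest (subject, lesion) pairs must be unique.",
          class = "radbiopsy_bad_manifest")
  }
  cases <- lapply(seq_len(nrow(man)), function(i) {
    for (col in c("volume_path", "lesion_path", "reference_path", "atlas_path")) {
      if (!file.exists(man[[col]][i])) {
        abort(paste0("Lesion ", man$lesion_id[i], ": missing file ", man[[col]][i]),
              class = "radbiopsy_missing_file")
      }
    }
    atl_vol <- read_volume(man$atlas_path[i])
    structure(
      list(volume = read_volume(man$volume_path[i]),
           lesion = as_mask(read_volume(man$lesion_path[i])),
           reference = as_mask(read_volume(man$reference_path[i])),
           atlas = atlas_parcellation(round(atl_vol$values), atl_vol$spacing),
           age = man$age[i], gender = man$gender[i],
           braf_status = as.character(man$braf_status[i]),
           seed_used = NA_integer_),
      class = "subject_case"
    )
  })
  structure(list(cases = cases, manifest = man, config = NULL),
            class = "synthetic_cohort")
}
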
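#' Percent of lesion volume in each of the 16 atlas regions
#'
#' Entry r is `100 * (#lesion voxels labeled r) / (#lesion voxels)`. Lesion
#' voxels on unlabeled (code 0) atlas voxels contribute to the denominator
#' only, so the percentages sum to 100 exactly when the lesion is fully
#' atlas-covered and to less otherwise.
#'
#' @param lesion Binary lesion mask (`image_volume` or array).
#' @param atlas An [atlas_parcellation()] on the same grid.
#' @return Named numeric vector of 16 percentages in `[0, 100]`.
#' @export
extract_location_features <- function(lesion, atlas) {
  lesion <- as_mask(lesion, atlas$spacing)
  if (!identical(lesion$shape, atlas$shape)) {
    abort("Lesion and atlas grids differ.", class = "radbiopsy_grid_mismatch")
  }
  idx <- lesion$values
  if (!any(idx)) abort("Lesion mask is empty.", class = "radbiopsy_empty_lesion")
  labs <- atlas$labels[idx]
  counts <- tabulate(labs, nbins = 16L)
  setNames(100 * counts / length(labs),
           paste0("location.", atlas$region_names))
}

#' Names of the 12 first-order features
#' @return Character vector in the fixed order used by the feature vector.
#' @export
first_order_names <- function() {
  c("mean", "median", "sd", "variance", "min", "max",
    "p5", "p25", "p75", "p95", "kurtosis", "skewness")
}

#' Twelve first-order intensity statistics over the lesion
#'
#' Histogram statistics of the in-lesion (normalized) intensities: mean,
#' median, sample SD and variance (divisor n-1), min, max, the 5/25/75/95th
#' percentiles (linear interpolation between order statistics), kurtosis
#' (biased fourth standardized moment, non-excess: a normal gives 3) and
#' skewness (biased third standardized moment). A zero-variance lesion emits
#' skewness and kurtosis 0 with a warning so the vector stays numeric.
#'
#' @param vol `image_volume`.
#' @param lesion Binary lesion mask on the same grid.
#' @return Named numeric vector of 12 values, prefixed `firstorder.`.
#' @export
extract_first_order_features <- function(vol, lesion) {
  stopifnot(inherits(vol, "image_volume"))
  lesion <- as_mask(lesion)
  assert_aligned(vol, lesion, "lesion mask")
  x <- vol$values[lesion$values]
  if (length(x) == 0L) abort("Lesion mask is empty.", class = "radbiopsy_empty_lesion")
  m <- mean(x)
  cx <- x - m
  m2 <- mean(cx^2)
  if (m2 == 0) {
    warn("Zero-variance lesion: skewness and kurtosis set to 0.")
    skew <- 0; kurt <- 0
  } else {
    skew <- mean(cx^3) / m2^1.5
    kurt <- mean(cx^4) / m2^2
  }
  qs <- quantile(x, c(0.05, 0.25, 0.75, 0.95), names = FALSE, type = 7)
  setNames(
    c(m, median(x), sd(x), var(x), min(x), max(x), qs, kurt, skew),
    paste0("firstorder.", first_order_names())
  )
}

#' The fixed, ordered 195 feature names
#'
#' 2 clinical + 16 location + 9 morphology + 12 first-order + 156 GLCM
#' (12 measures x 13 offsets at the configured distance). The same manifest
#' ships as `inst/extdata/feature_manifest.tsv`.
#'
#' @param distance GLCM displacement used in the texture feature names.
#' @return Character vector of length 195.
#' @export
feature_names <- function(distance = 8L) {
  offs <- rownames(glcm_offsets())
  glcm_nm <- unlist(lapply(haralick_names(), function(m) {
    paste0("glcm.", m, ".d", distance, "_", offs)
  }))
  c("clinical.age", "clinical.gender",
    paste0("location.", atlas_region_names()),
    paste0("morph.", morphology_names()),
    paste0("firstorder.", first_order_names()),
    glcm_nm)
}

#' Extract the full 195-feature vector for one subject case
#'
#' Normalizes the volume to its white-matter reference (unless
#' `normalize = FALSE`), then concatenates clinical (2), location (16),
#' morphology (9), first-order (12) and GLCM (156) features in the fixed
#' order of [feature_names()]. Deterministic for a fixed case. A failure in
#' any stage is rethrown with the feature family named.
#'
#' @param case A `subject_case` (from [generate_subject()] or [read_cohort()]).
#' @param config A [glcm_config()].
#' @param normalize Divide intensities by the reference-region mean first.
#' @return One-row tibble with 195 feature columns.
#' @export
extract_features <- function(case, config = glcm_config(), normalize = TRUE) {
  stopifnot(inherits(case, "subject_case"))
  vol <- if (normalize) normalize_to_reference(case$volume, case$reference)
         else case$volume
  stage <- function(family, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Feature extraction failed in family '", family, "': ",
                   conditionMessage(e)),
            class = "radbiopsy_feature_failure")
    })
  }
  clinical <- c(clinical.age = as.numeric(case$age),
                clinical.gender = as.numeric(case$gender))
  loc <- stage("location", extract_location_features(case$lesion, case$atlas))
  morph <- stage("morphology",
                 extract_morphology_features(case$lesion, case$lesion$spacing))
  names(morph) <- paste0("morph.", morphology_names())
  fo <- stage("first_order", extract_first_order_features(vol, case$lesion))
  glcm <- stage("glcm", extract_glcm_features(vol, case$lesion, config))
  out <- c(clinical, loc, morph, fo, glcm)
  stopifnot(identical(names(out), feature_names(config$distance)))
  as_tibble(as.list(out))
}

#' Extract features for every lesion of a cohort
#'
#' @param cohort A `synthetic_cohort` (or the list returned by
#'   [read_cohort()]).
#' @param config A [glcm_config()].
#' @param normalize Passed to [extract_features()].
#' @return Tibble: `subject_id`, `lesion_id`, `braf_status`, then the 195
#'   features, one row per lesion.
#' @export
extract_cohort_features <- function(cohort, config = glcm_config(),
                                    normalize = TRUE) {
  man <- cohort$manifest
  rows <- lapply(seq_along(cohort$cases), function(i) {
    tryCatch(
      extract_features(cohort$cases[[i]], config, normalize),
      error = function(e) {
        abort(paste0("Lesion ", man$lesion_id[i], ": ", conditionMessage(e)),
              class = "radbiopsy_feature_failure")
      }
    )
  })
  dplyr::bind_cols(
    tibble(subject_id = man$subject_id,
           lesion_id = man$lesion_id,
           braf_status = as.character(man$braf_status)),
    dplyr::bind_rows(rows)
  )
}
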
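#' 3D image volume
#'
#' Lightweight container for a 3D scalar grid with physical voxel spacing,
#' used for the contrast-enhanced T1-weighted image, binary masks, and any
#' derived grid. Intensities are stored as-is (arbitrary units); spacing is in
#' millimetres per axis.
#'
#' @param values 3D numeric array.
#' @param spacing Numeric length-3, strictly positive voxel size in mm.
#' @return An `image_volume`: a list with `values`, `spacing`, `shape`.
#' @examples
#' v <- image_volume(array(1, dim = c(4, 4, 4)))
#' v$shape
#' @export
image_volume <- function(values, spacing = c(1, 1, 1)) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    abort("`values` must be a 3D array, got a non-3D object.",
          class = "radbiopsy_not_3d")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be 3 strictly positive finite values (mm).",
          class = "radbiopsy_bad_spacing")
  }
  structure(
    list(values = values, spacing = spacing, shape = dim(values)),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(x$shape, collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' Binary segmentation mask on an image grid
#'
#' Coerces a volume (or array) to a binary mask. Any value strictly above 0.5
#' is foreground; used for lesion masks and the normal-appearing white-matter
#' reference region.
#'
#' @param x `image_volume` or 3D array.
#' @param spacing Spacing when `x` is a bare array.
#' @return An `image_volume` whose `values` are logical.
#' @export
as_mask <- function(x, spacing = c(1, 1, 1)) {
  if (inherits(x, "image_volume")) {
    image_volume(array(x$values > 0.5, dim = x$shape), x$spacing)
  } else {
    image_volume(array(x > 0.5, dim = dim(x)), spacing)
  }
}

#' Read a 3D NIfTI volume
#'
#' @param path Path to a `.nii` / `.nii.gz` file holding a 3D image.
#' @return An [image_volume()] with grid and spacing taken from the header.
#' @export
read_volume <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    abort(paste0("File not found: ", path), class = "radbiopsy_missing_file")
  }
  img <- tryCatch(
    RNifti::readNifti(path),
    error = function(e) abort(paste0("Unreadable NIfTI header/data in ", path,
                                     ": ", conditionMessage(e)),
                              class = "radbiopsy_unreadable")
  )
  d <- dim(img)
  if (length(d) != 3L) {
    abort(paste0("expected 3D volume, got ", length(d), "D in ", path),
          class = "radbiopsy_not_3d")
  }
  image_volume(array(as.numeric(img), dim = d),
               spacing = RNifti::pixdim(img)[1:3])
}

#' Write a volume to NIfTI-1
#'
#' @param vol `image_volume` (logical masks are written as 0/1).
#' @param path Destination `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  img <- RNifti::asNifti(array(as.numeric(vol$values), dim = vol$shape))
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) && all(abs(a$spacing - b$spacing) < tol)
}

assert_aligned <- function(a, b, what = "mask") {
  if (!same_grid(a, b)) {
    abort(paste0("Grid mismatch: ", what,
                 " must share the volume's shape and spacing."),
          class = "radbiopsy_grid_mismatch")
  }
  invisible(TRUE)
}

#' Normalize intensities to a reference region
#'
#' Divides every voxel by the mean intensity over a reference mask — in this
#' pipeline the normal-appearing white matter — so that images acquired on
#' different scanners and field strengths share a common intensity scale. The
#' mean of the output over the reference region is 1 by construction.
#'
#' @param vol `image_volume` to normalize.
#' @param reference Binary reference mask on the same grid, nonempty, with a
#'   nonzero mean intensity under `vol`.
#' @return Normalized `image_volume`.
#' @examples
#' v <- image_volume(array(100, dim = c(4, 4, 4)))
#' m <- as_mask(array(1, dim = c(4, 4, 4)))
#' range(normalize_to_reference(v, m)$values)  # all 1
#' @export
normalize_to_reference <- function(vol, reference) {
  stopifnot(inherits(vol, "image_volume"))
  reference <- as_mask(reference)
  assert_aligned(vol, reference, "reference mask")
  idx <- reference$values
  if (!any(idx)) {
    abort("Reference mask is empty; normalization undefined.",
          class = "radbiopsy_empty_reference")
  }
  m <- mean(vol$values[idx])
  if (!is.finite(m) || m == 0) {
    abort("Reference region mean is zero or non-finite; normalization undefined.",
          class = "radbiopsy_zero_reference")
  }
  image_volume(vol$values / m, vol$spacing)
}

#' Write a lesion-by-feature table to CSV
#'
#' One lesion per row; metadata columns (identifiers, label) first, then the
#' full ordered feature set. All rows must carry the identical 195 feature
#' names; the numeric round trip through [read_feature_table()] is lossless to
#' better than 1e-9.
#'
#' @param features Tibble from [extract_cohort_features()] (or compatible).
#' @param path Destination CSV path.
#' @param distance GLCM displacement used in the texture feature names;
#'   `NULL` auto-detects it from the column names (falling back to 8).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path, distance = NULL) {
  stopifnot(is.data.frame(features))
  if (is.null(distance)) {
    hit <- regmatches(names(features),
                      regexpr("(?<=^glcm\\.energy\\.d)[0-9]+", names(features),
                              perl = TRUE))
    distance <- if (length(hit) > 0) as.integer(hit[[1]]) else 8L
  }
  expected <- feature_names(distance)
  missing <- setdiff(expected, names(features))
  if (length(missing) > 0) {
    abort(paste0("Feature table is missing required feature(s): ",
                 paste(head(missing, 5), collapse = ", ")),
          class = "radbiopsy_missing_feature")
  }
  meta <- setdiff(names(features), expected)
  out <- features[, c(meta, expected), drop = FALSE]
  utils::write.csv(as.data.frame(out), path, row.names = FALSE)
  invisible(path)
}

#' Read a lesion-by-feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return Tibble with metadata columns followed by the 195 features.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "radbiopsy_missing_file")
  }
  as_tibble(utils::read.csv(path, check.names = FALSE))
}
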
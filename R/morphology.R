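# Label the largest 26-connected component of a 3D logical mask.
# Vectorized frontier BFS; returns a logical array of the same shape.
largest_component <- function(mask) {
  d <- dim(mask)
  idx_all <- which(mask)
  if (length(idx_all) == 0L) return(mask)
  # 26-neighbour linear-index offsets on a padded grid to avoid wrap-around
  dp <- d + 2L
  pad <- array(FALSE, dim = dp)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  lin_offs <- offs[, 1] + offs[, 2] * dp[1] + offs[, 3] * dp[1] * dp[2]
  remaining <- which(pad)
  visited <- array(FALSE, dim = dp)
  best <- integer(0)
  while (length(remaining) > 0L) {
    seedv <- remaining[1]
    comp <- seedv
    visited[seedv] <- TRUE
    frontier <- seedv
    while (length(frontier) > 0L) {
      nb <- unique(as.vector(outer(frontier, lin_offs, `+`)))
      nb <- nb[pad[nb] & !visited[nb]]
      visited[nb] <- TRUE
      comp <- c(comp, nb)
      frontier <- nb
    }
    if (length(comp) > length(best)) best <- comp
    remaining <- remaining[!visited[remaining]]
  }
  out_pad <- array(FALSE, dim = dp)
  out_pad[best] <- TRUE
  out_pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
}

# Iso-surface area (mm^2) of a binary mask via the coarea formula: the mask
# indicator is mildly Gaussian-smoothed and the gradient magnitude integrated
# over the grid. Exact for planar interfaces; curvature bias is small at the
# lesion scales used here.
surface_area_mask <- function(mask, spacing, sigma = 1.5) {
  w <- which(mask, arr.ind = TRUE)
  lo <- pmax(1L, apply(w, 2, min) - 6L)
  hi <- pmin(dim(mask), apply(w, 2, max) + 6L)
  sub <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  d <- dim(sub)
  pad <- 6L
  u <- array(0, dim = d + 2L * pad)
  u[(pad + 1):(pad + d[1]), (pad + 1):(pad + d[2]), (pad + 1):(pad + d[3])] <-
    as.numeric(sub)
  u <- smooth_gaussian3(u, sigma)
  dd <- dim(u)
  gx <- array(0, dim = dd); gy <- gx; gz <- gx
  gx[2:(dd[1] - 1), , ] <- (u[3:dd[1], , ] - u[1:(dd[1] - 2), , ]) / (2 * spacing[1])
  gy[, 2:(dd[2] - 1), ] <- (u[, 3:dd[2], ] - u[, 1:(dd[2] - 2), ]) / (2 * spacing[2])
  gz[, , 2:(dd[3] - 1)] <- (u[, , 3:dd[3]] - u[, , 1:(dd[3] - 2)]) / (2 * spacing[3])
  sum(sqrt(gx^2 + gy^2 + gz^2)) * prod(spacing)
}

#' Names of the 9 morphology features
#' @return Character vector in the fixed order used by the feature vector.
#' @export
morphology_names <- function() {
  c("volume_mm3", "equiv_diameter_mm", "extent",
    "principal_axis_1_mm", "principal_axis_2_mm", "principal_axis_3_mm",
    "convex_volume_mm3", "solidity", "surface_area_mm2")
}

#' Nine 3D morphology features of a lesion mask
#'
#' Computed on the largest 26-connected component (a warning is raised when
#' the mask has more than one component):
#' volume = voxel count x voxel volume (mm^3); equivalent diameter =
#' `(6 V / pi)^(1/3)` (mm); extent = volume / bounding-box volume; the three
#' principal axis lengths are the uniform-ellipsoid-equivalent lengths
#' `2 sqrt(5 lambda_i)` from the eigenvalues of the voxel-center covariance in
#' physical units (population divisor, plus the `spacing^2 / 12` cell-spread
#' term, sorted descending); convex volume = voxelized convex hull volume;
#' solidity = volume / convex volume; surface area = integrated iso-surface
#' area (mm^2).
#'
#' @param lesion Binary mask as `image_volume` (or 3D array with `spacing`).
#' @param spacing Voxel spacing when `lesion` is a bare array.
#' @return Named numeric vector of 9 features.
#' @examples
#' cube <- array(FALSE, dim = c(16, 16, 16)); cube[4:13, 4:13, 4:13] <- TRUE
#' extract_morphology_features(cube)[c("volume_mm3", "solidity")]
#' @export
extract_morphology_features <- function(lesion, spacing = c(1, 1, 1)) {
  lesion <- as_mask(lesion, spacing)
  spacing <- lesion$spacing
  mask <- lesion$values
  if (!any(mask)) abort("Lesion mask is empty.", class = "radbiopsy_empty_lesion")
  lab <- largest_component(mask)
  if (sum(lab) < sum(mask)) {
    warn("Lesion mask has multiple connected components; analyzing the largest.")
    mask <- lab
  }
  w <- which(mask, arr.ind = TRUE)
  n <- nrow(w)
  vox_vol <- prod(spacing)
  volume <- n * vox_vol
  equiv_diam <- (6 * volume / pi)^(1 / 3)
  bbox <- prod((apply(w, 2, max) - apply(w, 2, min) + 1) * spacing)
  extent <- volume / bbox
  coords <- sweep(w, 2, spacing, `*`)
  cc <- sweep(coords, 2, colMeans(coords))
  covm <- crossprod(cc) / n + diag(spacing^2 / 12)
  lambda <- sort(eigen(covm, symmetric = TRUE, only.values = TRUE)$values,
                 decreasing = TRUE)
  axes <- 2 * sqrt(5 * pmax(lambda, 0))
  cvol <- convex_volume_mask(mask, spacing)
  sa <- surface_area_mask(mask, spacing)
  setNames(
    c(volume, equiv_diam, extent, axes, cvol, volume / cvol, sa),
    morphology_names()
  )
}
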
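#' The 16 brain regions used for lesion location features
#'
#' Left/right frontal, parietal, temporal, occipital, limbic, sublobar,
#' cerebellum, and brainstem — the lobar-level parcellation of the Talairach
#' stereotactic atlas. Label codes 1..16 follow this order; 0 is unlabeled.
#'
#' @return Character vector of 16 region names.
#' @export
atlas_region_names <- function() {
  structures <- c("frontal", "parietal", "temporal", "occipital",
                  "limbic", "sublobar", "cerebellum", "brainstem")
  paste(rep(structures, each = 2), c("left", "right"), sep = "_")
}

#' Atlas parcellation container
#'
#' @param labels 3D integer array with codes 0 (unlabeled) and 1-16.
#' @param spacing Voxel spacing (mm).
#' @return An `atlas_parcellation` with `labels`, `region_names`, `spacing`,
#'   `shape`.
#' @export
atlas_parcellation <- function(labels, spacing = c(1, 1, 1)) {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    abort("`labels` must be a 3D array.", class = "radbiopsy_not_3d")
  }
  codes <- sort(unique(as.integer(labels)))
  if (any(codes < 0L) || any(codes > 16L)) {
    abort("Atlas labels must lie in 0..16.", class = "radbiopsy_bad_atlas")
  }
  structure(
    list(labels = array(as.integer(labels), dim = dim(labels)),
         region_names = atlas_region_names(),
         spacing = as.numeric(spacing), shape = dim(labels)),
    class = "atlas_parcellation"
  )
}

# Equal-length split of 1..n into k contiguous blocks (sizes differ by <= 1).
split_blocks <- function(n, k) {
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  Map(seq.int, starts, ends)
}

#' Build a deterministic 16-region grid atlas
#'
#' Surrogate parcellation for synthetic subjects: a "brain" interior box
#' (12.5% margin on each face) partitioned into 16 contiguous rectangular
#' blocks labeled 1..16 — the left/right halves of 8 structure slabs — with
#' the exterior labeled 0. Purely geometric and seed-free: two calls with the
#' same shape give identical label grids.
#'
#' @param grid_shape Integer length-3, each dimension >= 16.
#' @param spacing Voxel spacing (mm).
#' @return An [atlas_parcellation()].
#' @examples
#' atl <- build_grid_atlas(c(32, 32, 32))
#' table(atl$labels)["0"]
#' @export
build_grid_atlas <- function(grid_shape, spacing = c(1, 1, 1)) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 16L)) {
    abort("Grid too small for a 16-region parcellation: every dimension must be >= 16.",
          class = "radbiopsy_grid_too_small")
  }
  labels <- array(0L, dim = grid_shape)
  margin <- pmax(1L, grid_shape %/% 8L)
  interior <- Map(function(n, m) seq.int(m + 1L, n - m), grid_shape, margin)
  # x split: left/right; y split: 4 slabs; z split: 2 slabs -> 8 structures x 2 sides
  xs <- split_blocks(length(interior[[1]]), 2L)
  ys <- split_blocks(length(interior[[2]]), 4L)
  zs <- split_blocks(length(interior[[3]]), 2L)
  for (side in 1:2) {
    for (iy in 1:4) {
      for (iz in 1:2) {
        structure_idx <- (iz - 1L) * 4L + iy       # 1..8
        code <- (structure_idx - 1L) * 2L + side    # 1..16
        labels[interior[[1]][xs[[side]]],
               interior[[2]][ys[[iy]]],
               interior[[3]][zs[[iz]]]] <- code
      }
    }
  }
  atlas_parcellation(labels, spacing)
}

# Bounding index ranges (list of 3 integer vectors) of a given atlas code.
atlas_region_box <- function(atlas, code) {
  w <- which(atlas$labels == code, arr.ind = TRUE)
  lapply(1:3, function(a) range(w[, a]))
}
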
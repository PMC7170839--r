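#' The 13 canonical 3D co-occurrence offsets
#'
#' The non-antiparallel half of the 26-neighbourhood: the 4 in-plane
#' directions (0, 45, 90, 135 degrees) plus 9 out-of-plane directions that
#' carry the 3D information. Because the co-occurrence matrix is accumulated
#' symmetrically, an offset and its negation are equivalent, so 13 directions
#' cover all 26 neighbours.
#'
#' @return 13 x 3 integer matrix; rownames `o1`..`o13`, with an `angle`
#'   attribute giving the conventional in-plane/through-plane angle label.
#' @export
glcm_offsets <- function() {
  m <- rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 0), c(1, -1, 0),
    c(1, 0, 1), c(1, 0, -1),
    c(0, 1, 1), c(0, 1, -1),
    c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1)
  )
  storage.mode(m) <- "integer"
  rownames(m) <- paste0("o", 1:13)
  colnames(m) <- c("dx", "dy", "dz")
  attr(m, "angle") <- c(
    "0 (in-plane)", "90 (in-plane)", "axial",
    "45 (in-plane)", "135 (in-plane)",
    "0/45", "0/135", "90/45", "90/135",
    "45/45", "45/135", "135/45", "135/135"
  )
  m
}

#' GLCM computation settings
#'
#' @param n_levels Gray-level count for quantization (>= 2). Default 32
#'   equal-width bins over the in-lesion intensity range.
#' @param distance Inter-voxel displacement multiplier in voxels (>= 1);
#'   default 8. Diagonal offsets use the same multiplier per component
#'   (displacement = distance x direction vector), not an equalized Euclidean
#'   length.
#' @return A `glcm_config` list with `n_levels`, `distance`, `offsets`.
#' @export
glcm_config <- function(n_levels = 32L, distance = 8L) {
  n_levels <- as.integer(n_levels)
  distance <- as.integer(distance)
  if (n_levels < 2L) abort("n_levels must be >= 2.", class = "radbiopsy_bad_config")
  if (distance < 1L) abort("distance must be >= 1.", class = "radbiopsy_bad_config")
  structure(list(n_levels = n_levels, distance = distance,
                 offsets = glcm_offsets()),
            class = "glcm_config")
}

#' Quantize in-lesion intensities to discrete gray levels
#'
#' Equal-width bins between the in-lesion minimum and maximum map intensities
#' to levels `1..n_levels`; the maximum falls in the top bin. A constant
#' lesion maps wholly to level 1. Voxels outside the lesion carry `NA`. The
#' mapping is range-relative, so scaling intensities by a positive constant
#' leaves the quantized grid (and every downstream texture feature) unchanged.
#'
#' @param vol `image_volume`.
#' @param lesion Binary lesion mask on the same grid, nonempty.
#' @param n_levels Number of gray levels.
#' @return Integer 3D array, `NA` outside the lesion.
#' @export
quantize_lesion <- function(vol, lesion, n_levels = 32L) {
  stopifnot(inherits(vol, "image_volume"))
  lesion <- as_mask(lesion)
  assert_aligned(vol, lesion, "lesion mask")
  idx <- lesion$values
  if (!any(idx)) {
    abort("Lesion mask is empty.", class = "radbiopsy_empty_lesion")
  }
  n_levels <- as.integer(n_levels)
  x <- vol$values[idx]
  lo <- min(x); hi <- max(x)
  q <- array(NA_integer_, dim = vol$shape)
  if (hi == lo) {
    q[idx] <- 1L
  } else {
    lev <- floor((x - lo) / (hi - lo) * n_levels) + 1L
    q[idx] <- pmin(as.integer(lev), n_levels)
  }
  q
}

#' Compute one symmetric gray-level co-occurrence matrix
#'
#' Counts pairs of in-lesion voxels `(v, v + distance * offset)`, accumulates
#' each pair in both orders (Haralick's symmetric convention), and normalizes
#' to a probability matrix. Pairs with either voxel outside the lesion are
#' discarded. When the lesion is thinner than the displacement there are no
#' valid pairs: the matrix is all-zero with `pair_count` 0 and downstream
#' measures emit `NA`.
#'
#' @param quantized Integer array from [quantize_lesion()] (`NA` = outside).
#' @param offset Length-3 integer direction (one of the 13 canonical rows of
#'   [glcm_offsets()]).
#' @param distance Displacement multiplier in voxels.
#' @param n_levels Gray-level count (defaults to the max observed level).
#' @return A `glcm`: list with `probabilities` (n_levels x n_levels),
#'   `pair_count` (number of distinct ordered source pairs found along the
#'   offset), `offset`, `distance`.
#' @export
compute_glcm <- function(quantized, offset, distance = 8L, n_levels = NULL) {
  stopifnot(is.array(quantized), length(dim(quantized)) == 3L)
  offset <- as.integer(offset)
  if (length(offset) != 3L || all(offset == 0L)) {
    abort("offset must be a nonzero length-3 integer direction.",
          class = "radbiopsy_bad_offset")
  }
  if (is.null(n_levels)) n_levels <- max(quantized, na.rm = TRUE)
  n_levels <- as.integer(n_levels)
  d <- as.integer(offset) * as.integer(distance)
  dm <- dim(quantized)
  rng <- lapply(1:3, function(a) {
    lo <- max(1L, 1L - d[a]); hi <- min(dm[a], dm[a] - d[a])
    if (hi < lo) integer(0) else seq.int(lo, hi)
  })
  L <- n_levels
  if (any(lengths(rng) == 0L)) {
    counts <- matrix(0, L, L)
    pair_count <- 0L
  } else {
    a <- quantized[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    b <- quantized[rng[[1]] + d[1], rng[[2]] + d[2], rng[[3]] + d[3], drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    pair_count <- sum(ok)
    if (pair_count == 0L) {
      counts <- matrix(0, L, L)
    } else {
      tab <- tabulate((a[ok] - 1L) * L + b[ok], nbins = L * L)
      counts <- matrix(tab, L, L, byrow = TRUE)  # row = first voxel's level
      counts <- counts + t(counts)               # symmetric accumulation
    }
  }
  total <- sum(counts)
  probs <- if (total > 0) counts / total else counts
  structure(list(probabilities = probs, pair_count = as.integer(pair_count),
                 offset = offset, distance = as.integer(distance),
                 n_levels = L),
            class = "glcm")
}

#' Names of the 12 co-occurrence (Haralick) measures
#' @return Character vector of 12 measure names in their fixed order.
#' @export
haralick_names <- function() {
  c("energy", "entropy", "correlation", "contrast", "variance", "sum_mean",
    "inertia", "cluster_shade", "cluster_tendency", "homogeneity",
    "max_probability", "inverse_variance")
}

#' Twelve Haralick-style measures of a co-occurrence matrix
#'
#' For a symmetric probability matrix `p(i, j)` over levels `1..L` with
#' marginal mean `mu` and SD `sigma` (row and column marginals coincide):
#' energy = sum p^2; entropy = -sum p log2 p (0 log 0 = 0); correlation =
#' sum (i - mu)(j - mu) p / sigma^2 (0 when sigma = 0); contrast = inertia =
#' sum (i - j)^2 p; variance = sum (i - mu)^2 p; sum_mean = 1/2 sum (i + j) p;
#' cluster_shade = sum (i + j - 2 mu)^3 p; cluster_tendency =
#' sum (i + j - 2 mu)^2 p; homogeneity = sum p / (1 + |i - j|);
#' max_probability = max p; inverse_variance = sum over i != j of
#' p / (i - j)^2.
#'
#' A GLCM with no contributing pairs yields `NA` for every measure.
#'
#' @param g A `glcm` from [compute_glcm()].
#' @return Named numeric vector of the 12 measures.
#' @export
haralick_measures <- function(g) {
  stopifnot(inherits(g, "glcm"))
  nm <- haralick_names()
  if (g$pair_count == 0L) {
    return(setNames(rep(NA_real_, 12L), nm))
  }
  p <- g$probabilities
  L <- nrow(p)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  pi_marg <- rowSums(p)                      # symmetric: row = col marginal
  mu <- sum(seq_len(L) * pi_marg)
  sigma2 <- sum((seq_len(L) - mu)^2 * pi_marg)
  pos <- p > 0
  entropy <- -sum(p[pos] * log2(p[pos]))
  contrast <- sum((i - j)^2 * p)
  correlation <- if (sigma2 > 0) sum((i - mu) * (j - mu) * p) / sigma2 else 0
  off_diag <- i != j
  setNames(c(
    sum(p^2),
    entropy,
    correlation,
    contrast,
    sigma2,
    0.5 * sum((i + j) * p),
    contrast,
    sum((i + j - 2 * mu)^3 * p),
    sum((i + j - 2 * mu)^2 * p),
    sum(p / (1 + abs(i - j))),
    max(p),
    sum(p[off_diag] / (i[off_diag] - j[off_diag])^2)
  ), nm)
}

#' All 156 co-occurrence texture features of a lesion
#'
#' Quantizes the in-lesion intensities, computes one symmetric GLCM per
#' canonical offset at the configured distance, and evaluates the 12 measures
#' on each: 12 x 13 = 156 features named
#' `glcm.<measure>.d<distance>_o<offset>`.
#'
#' @param vol Normalized `image_volume`.
#' @param lesion Binary lesion mask.
#' @param config A [glcm_config()].
#' @return Named numeric vector of 156 values.
#' @export
extract_glcm_features <- function(vol, lesion, config = glcm_config()) {
  q <- quantize_lesion(vol, lesion, config$n_levels)
  offs <- config$offsets
  vals <- lapply(seq_len(nrow(offs)), function(k) {
    g <- compute_glcm(q, offs[k, ], config$distance, config$n_levels)
    haralick_measures(g)
  })
  out <- numeric(0)
  for (m in seq_along(haralick_names())) {
    v <- vapply(vals, `[[`, numeric(1), m)
    names(v) <- paste0("glcm.", haralick_names()[m], ".d", config$distance,
                       "_", rownames(offs))
    out <- c(out, v)
  }
  out
}
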
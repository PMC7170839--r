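# Shared fixtures and independent oracles, all built in code.

make_cube_mask <- function(dim = c(16, 16, 16), from = 4, to = 13) {
  m <- array(FALSE, dim = dim)
  m[from:to, from:to, from:to] <- TRUE
  m
}

make_ball_mask <- function(radius, dim = rep(2 * radius + 10, 3),
                           center = (dim + 1) / 2) {
  w <- as.matrix(expand.grid(seq_len(dim[1]), seq_len(dim[2]), seq_len(dim[3])))
  m <- array(FALSE, dim = dim)
  m[w[rowSums(sweep(w, 2, center)^2) <= radius^2, ]] <- TRUE
  m
}

# Small random blob-ish lesion: a ball with seeded noise thresholding.
random_lesion <- function(seed, dim = c(12, 12, 12)) {
  set.seed(seed)
  m <- array(runif(prod(dim)) < 0.45, dim = dim)
  ctr <- (dim + 1) / 2
  w <- as.matrix(expand.grid(seq_len(dim[1]), seq_len(dim[2]), seq_len(dim[3])))
  near <- array(FALSE, dim = dim)
  near[w[rowSums(sweep(w, 2, ctr)^2) <= (min(dim) / 2 - 1)^2, ]] <- TRUE
  m & near
}

# Fast-to-generate cohort config for unit tests (small grid, small lesions).
small_config <- function(...) {
  cohort_config(grid_shape = c(32L, 32L, 32L), lesion_radius_range = c(4, 6), ...)
}

# Exhaustive voxel-pair enumeration oracle for the symmetric GLCM.
glcm_oracle <- function(quantized, offset, distance, n_levels) {
  d <- dim(quantized)
  counts <- matrix(0, n_levels, n_levels)
  pair_count <- 0L
  step <- offset * distance
  idx <- which(!is.na(quantized), arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]
    u <- v + step
    if (all(u >= 1) && all(u <= d)) {
      b <- quantized[u[1], u[2], u[3]]
      if (!is.na(b)) {
        a <- quantized[v[1], v[2], v[3]]
        counts[a, b] <- counts[a, b] + 1
        counts[b, a] <- counts[b, a] + 1
        pair_count <- pair_count + 1L
      }
    }
  }
  tot <- sum(counts)
  list(probabilities = if (tot > 0) counts / tot else counts,
       pair_count = pair_count)
}

# Exhaustive pairwise-comparison AUC oracle (ties count 0.5).
auc_oracle <- function(scores, truth) {
  sp <- scores[truth == "positive"]
  sn <- scores[truth == "negative"]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# One case wrapper for feature-extraction tests.
manual_case <- function(values, lesion, reference = NULL, atlas = NULL,
                        spacing = c(1, 1, 1), age = 60, gender = 0,
                        braf_status = "positive") {
  d <- dim(values)
  if (is.null(reference)) {
    reference <- array(FALSE, dim = d)
    reference[1:2, 1:2, 1:2] <- TRUE
  }
  if (is.null(atlas)) atlas <- build_grid_atlas(d, spacing)
  structure(
    list(volume = image_volume(values, spacing),
         lesion = as_mask(lesion, spacing),
         reference = as_mask(reference, spacing),
         atlas = atlas, age = age, gender = gender,
         braf_status = braf_status, seed_used = NA_integer_),
    class = "subject_case"
  )
}
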
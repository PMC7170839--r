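test_that("quantization maps the in-lesion range onto 1..n_levels", {
  d <- c(6, 6, 6)
  lesion <- array(TRUE, dim = d)
  # constant lesion -> all level 1
  q <- quantize_lesion(image_volume(array(5, dim = d)), lesion, 4)
  expect_true(all(q == 1L))
  # endpoints of [0, 1] at 4 levels
  vals <- array(runif(prod(d)), dim = d)
  vals[1, 1, 1] <- 0; vals[6, 6, 6] <- 1
  q2 <- quantize_lesion(image_volume(vals), lesion, 4)
  expect_identical(q2[1, 1, 1], 1L)
  expect_identical(q2[6, 6, 6], 4L)
  expect_true(all(q2 >= 1 & q2 <= 4))
  # out-of-lesion voxels carry the NA sentinel
  half <- array(FALSE, dim = d); half[1:3, , ] <- TRUE
  q3 <- quantize_lesion(image_volume(vals), half, 4)
  expect_true(all(is.na(q3[4:6, , ])))
  expect_error(quantize_lesion(image_volume(vals), array(FALSE, dim = d), 4),
               class = "radbiopsy_empty_lesion")
})

test_that("uniform intensities fill quantization levels evenly", {
  set.seed(5)
  d <- c(50, 50, 40)   # 1e5 voxels
  vals <- array(runif(prod(d)), dim = d)
  q <- quantize_lesion(image_volume(vals), array(TRUE, dim = d), 8)
  share <- 100 * tabulate(q, 8) / prod(d)
  expect_true(all(abs(share - 12.5) < 3))
})

test_that("the 3-voxel row example gives the hand-computed symmetric GLCM", {
  q <- array(NA_integer_, dim = c(3, 1, 1))
  q[, 1, 1] <- c(1L, 1L, 2L)
  g <- compute_glcm(q, c(1, 0, 0), distance = 1, n_levels = 2)
  expect_identical(g$pair_count, 2L)
  expect_equal(g$probabilities,
               matrix(c(0.5, 0.25, 0.25, 0), 2, 2), tolerance = 0)
})

test_that("degenerate GLCMs behave as specified", {
  d <- c(4, 4, 4)
  q <- quantize_lesion(image_volume(array(1, dim = d)), array(TRUE, dim = d), 8)
  g <- compute_glcm(q, c(1, 0, 0), distance = 1, n_levels = 8)
  expect_equal(g$probabilities[1, 1], 1)        # constant lesion: point mass
  # lesion thinner than the displacement: no pairs, measures go NA
  g0 <- compute_glcm(q, c(1, 0, 0), distance = 8, n_levels = 8)
  expect_identical(g0$pair_count, 0L)
  expect_equal(sum(g0$probabilities), 0)
  expect_true(all(is.na(haralick_measures(g0))))
})

test_that("compute_glcm matches exhaustive pair enumeration on random lesions", {
  offsets <- glcm_offsets()
  for (seed in c(2, 9)) {
    lesion <- random_lesion(seed)
    set.seed(seed + 100)
    vals <- array(rnorm(prod(dim(lesion))), dim = dim(lesion))
    q <- quantize_lesion(image_volume(vals), lesion, 6)
    for (k in seq_len(nrow(offsets))) {
      for (dist in c(1L, 3L, 8L)) {
        got <- compute_glcm(q, offsets[k, ], dist, n_levels = 6)
        want <- glcm_oracle(q, offsets[k, ], dist, 6)
        expect_identical(got$pair_count, want$pair_count)
        expect_equal(got$probabilities, want$probabilities, tolerance = 0)
      }
    }
  }
})

test_that("haralick measures agree with hand summation", {
  pm <- function(p, n) structure(list(probabilities = p, pair_count = n,
                                      n_levels = nrow(p), offset = c(1, 0, 0),
                                      distance = 1L), class = "glcm")
  # point mass
  h <- haralick_measures(pm(matrix(c(1, 0, 0, 0), 2, 2), 2L))
  expect_equal(h[["energy"]], 1)
  expect_equal(h[["entropy"]], 0)
  expect_equal(h[["contrast"]], 0)
  expect_equal(h[["max_probability"]], 1)
  # uniform 4x4
  h4 <- haralick_measures(pm(matrix(1 / 16, 4, 4), 8L))
  expect_equal(h4[["energy"]], 1 / 16)
  expect_equal(h4[["entropy"]], 4)
  # the worked 2x2 example
  p <- matrix(c(0.5, 0.25, 0.25, 0), 2, 2)
  h2 <- haralick_measures(pm(p, 2L))
  expect_equal(h2[["contrast"]], 0.5)
  expect_equal(h2[["max_probability"]], 0.5)
  expect_equal(h2[["inertia"]], h2[["contrast"]])
  # against full brute-force sums on a random symmetric matrix
  set.seed(1)
  m <- matrix(runif(25), 5, 5); m <- m + t(m); m <- m / sum(m)
  h5 <- haralick_measures(pm(m, 10L))
  mu <- sum(rowSums(m) * 1:5)
  brute <- c(energy = 0, entropy = 0, contrast = 0, variance = 0,
             sum_mean = 0, shade = 0, tend = 0, homog = 0, invvar = 0,
             corrnum = 0)
  for (i in 1:5) for (j in 1:5) {
    p_ij <- m[i, j]
    brute["energy"] <- brute["energy"] + p_ij^2
    if (p_ij > 0) brute["entropy"] <- brute["entropy"] - p_ij * log2(p_ij)
    brute["contrast"] <- brute["contrast"] + (i - j)^2 * p_ij
    brute["variance"] <- brute["variance"] + (i - mu)^2 * p_ij
    brute["sum_mean"] <- brute["sum_mean"] + 0.5 * (i + j) * p_ij
    brute["shade"] <- brute["shade"] + (i + j - 2 * mu)^3 * p_ij
    brute["tend"] <- brute["tend"] + (i + j - 2 * mu)^2 * p_ij
    brute["homog"] <- brute["homog"] + p_ij / (1 + abs(i - j))
    if (i != j) brute["invvar"] <- brute["invvar"] + p_ij / (i - j)^2
    brute["corrnum"] <- brute["corrnum"] + (i - mu) * (j - mu) * p_ij
  }
  expect_equal(h5[["energy"]], brute[["energy"]])
  expect_equal(h5[["entropy"]], brute[["entropy"]])
  expect_equal(h5[["contrast"]], brute[["contrast"]])
  expect_equal(h5[["variance"]], brute[["variance"]])
  expect_equal(h5[["sum_mean"]], brute[["sum_mean"]])
  expect_equal(h5[["cluster_shade"]], brute[["shade"]])
  expect_equal(h5[["cluster_tendency"]], brute[["tend"]])
  expect_equal(h5[["homogeneity"]], brute[["homog"]])
  expect_equal(h5[["inverse_variance"]], brute[["invvar"]])
  expect_equal(h5[["correlation"]], brute[["corrnum"]] / brute[["variance"]])
})

test_that("GLCM features are invariant to positive intensity scaling", {
  lesion <- random_lesion(4, dim = c(14, 14, 14))
  set.seed(21)
  vals <- array(rexp(prod(dim(lesion))), dim = dim(lesion))
  cfg <- glcm_config(n_levels = 16, distance = 2)
  f1 <- extract_glcm_features(image_volume(vals), lesion, cfg)
  f2 <- extract_glcm_features(image_volume(vals * 3.7), lesion, cfg)
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("rotating a lesion by 90 degrees permutes the per-offset features", {
  lesion <- random_lesion(8, dim = c(14, 14, 14))
  set.seed(30)
  vals <- array(rnorm(prod(dim(lesion))), dim = dim(lesion))
  cfg <- glcm_config(n_levels = 8, distance = 2)
  rot_z <- function(a) {             # (x, y) -> (-y, x)
    b <- aperm(a, c(2, 1, 3))
    b[rev(seq_len(dim(b)[1])), , , drop = FALSE]
  }
  f_orig <- extract_glcm_features(image_volume(vals), lesion, cfg)
  f_rot <- extract_glcm_features(image_volume(rot_z(vals)), rot_z(lesion), cfg)
  offs <- glcm_offsets()
  canon <- function(v) if (v[which(v != 0)[1]] < 0) -v else v
  for (k in seq_len(nrow(offs))) {
    mapped <- canon(c(-offs[k, 2], offs[k, 1], offs[k, 3]))
    k2 <- which(apply(offs, 1, function(o) all(o == mapped)))
    expect_length(k2, 1L)
    for (m in haralick_names()) {
      expect_equal(
        f_rot[[paste0("glcm.", m, ".d2_o", k2)]],
        f_orig[[paste0("glcm.", m, ".d2_o", k)]],
        tolerance = 1e-9
      )
    }
  }
})

test_that("entropy rises and energy falls as texture correlation shortens", {
  mask <- make_ball_mask(7, dim = c(20, 20, 20))
  mean_measures <- function(sigma, seed) {
    set.seed(seed)
    field <- radbiopsy:::smooth_gaussian3(array(rnorm(20^3), dim = c(20, 20, 20)),
                                          sigma)
    f <- extract_glcm_features(image_volume(field), mask,
                               glcm_config(n_levels = 16, distance = 2))
    c(entropy = mean(f[grepl("entropy", names(f))]),
      energy = mean(f[grepl("energy", names(f))]))
  }
  res_short <- rowMeans(vapply(1:5, function(s) mean_measures(1, s), numeric(2)))
  res_long <- rowMeans(vapply(1:5, function(s) mean_measures(3, s), numeric(2)))
  expect_gt(res_short[["entropy"]], res_long[["entropy"]])
  expect_lt(res_short[["energy"]], res_long[["energy"]])
})
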
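# Run code with a temporary RNG state; the caller's .Random.seed is restored.
with_rng_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Counter-based child-seed derivation (Lehmer-style, mod 2^31 - 1) so every
# per-subject stream is reproducible from one master seed across platforms.
derive_seed <- function(master, counter) {
  m <- 2147483647
  s <- ((as.double(master) %% m) * 48271 + as.double(counter) * 104729) %% m
  as.integer(max(1, s))
}

# Row-normalized Gaussian band matrix for 1D smoothing along one axis.
gauss_band <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  k <- max(1L, ceiling(3 * sigma))
  off <- -k:k
  w <- dnorm(off, 0, sigma)
  w <- w / sum(w)
  A <- matrix(0, n, n)
  for (o in seq_along(off)) {
    src <- seq_len(n) + off[o]
    ok <- src >= 1L & src <= n
    A[cbind(which(ok), src[ok])] <- A[cbind(which(ok), src[ok])] + w[o]
  }
  A
}

# Separable 3D Gaussian smoothing, sigma in voxel units (scalar or length 3).
smooth_gaussian3 <- function(arr, sigma) {
  d <- dim(arr)
  sigma <- rep(sigma, length.out = 3)
  x <- array(gauss_band(d[1], sigma[1]) %*% matrix(arr, d[1]), dim = d)
  y <- aperm(x, c(2, 1, 3))
  y <- array(gauss_band(d[2], sigma[2]) %*% matrix(y, d[2]), dim = d[c(2, 1, 3)])
  x <- aperm(y, c(2, 1, 3))
  z <- aperm(x, c(3, 1, 2))
  z <- array(gauss_band(d[3], sigma[3]) %*% matrix(z, d[3]), dim = d[c(3, 1, 2)])
  aperm(z, c(2, 3, 1))
}

# Population standard deviation (divisor n).
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

as_binary_label <- function(x) {
  f <- factor(as.character(x), levels = c("negative", "positive"))
  if (anyNA(f)) {
    abort("Class labels must be 'positive'/'negative'.",
          class = "radbiopsy_bad_label")
  }
  f
}
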
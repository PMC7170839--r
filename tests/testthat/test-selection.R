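test_that("KS normality verdicts are calibrated on normal and non-normal data", {
  verdicts <- vapply(1:50, function(s) {
    set.seed(s)
    test_normality(rnorm(200))$verdict
  }, character(1))
  expect_gte(mean(verdicts == "normal"), 0.9)
  set.seed(1)
  two_point <- sample(c(0, 10), 200, replace = TRUE)
  expect_equal(test_normality(two_point)$verdict, "non-normal")
  # degenerate inputs give the sentinel
  const <- test_normality(rep(3, 10))
  expect_equal(const$verdict, "non-normal")
  expect_true(is.na(const$p))
  expect_true(is.na(test_normality(c(1, 2))$p))
})

test_that("group difference tests behave at the extremes and choose branches", {
  same <- group_difference_test(1:10, 1:10)
  expect_gte(same$p, 0.99)
  far <- group_difference_test(1:10, 101:110)
  expect_lt(far$p, 0.001)
  # normal data -> pooled t; heavy ties -> Mann-Whitney
  set.seed(3)
  r <- group_difference_test(rnorm(50), rnorm(50))
  expect_equal(r$test, "t")
  r2 <- group_difference_test(sample(c(0, 1), 50, TRUE), sample(c(0, 1), 50, TRUE))
  expect_equal(r2$test, "mann_whitney")
  expect_error(group_difference_test(1, 1:5), class = "radbiopsy_bad_groups")
})

test_that("selection finds an injected signal and respects alpha boundaries", {
  set.seed(12)
  n <- 30
  labels <- rep(c("positive", "negative"), each = n / 2)
  null_feats <- as.data.frame(matrix(rnorm(n * 40), n,
                                     dimnames = list(NULL, paste0("f", 1:40))))
  null_feats$signal <- (labels == "positive") + rnorm(n, sd = 0.1)
  tbl <- dplyr::bind_cols(tibble::tibble(braf_status = labels), null_feats)
  rep1 <- select_features(tbl, features = c(paste0("f", 1:40), "signal"))
  expect_true("signal" %in% attr(rep1, "selected"))
  expect_s3_class(tidy(rep1), "tbl_df")
  expect_equal(glance(rep1)$n_features, 41L)
  # alpha = 0 selects nothing
  rep0 <- select_features(tbl, features = paste0("f", 1:40), alpha = 0)
  expect_length(attr(rep0, "selected"), 0L)
  # single-class input errors
  tbl1 <- tbl[tbl$braf_status == "positive", ]
  expect_error(select_features(tbl1, features = "f1"),
               class = "radbiopsy_single_class")
})

test_that("an all-null 195-feature table selects a binomial-consistent count", {
  set.seed(77)
  n <- 54
  labels <- rep(c("positive", "negative"), c(25, 29))
  feats <- as.data.frame(matrix(rnorm(n * 195), n,
                                dimnames = list(NULL, paste0("f", 1:195))))
  tbl <- dplyr::bind_cols(tibble::tibble(braf_status = labels), feats)
  rep_null <- select_features(tbl, features = paste0("f", 1:195))
  n_sel <- sum(rep_null$selected)
  expect_gte(n_sel, 2L)   # binomial(195, 0.05) bounds
  expect_lte(n_sel, 20L)
})

test_that("standardization centers and scales with the sample-SD convention", {
  tbl <- tibble::tibble(a = c(1, 2, 3), b = c(10, 30, 20), k = c(5, 5, 5))
  expect_warning(std <- standardize_features(tbl, c("a", "b", "k")),
                 "zero-spread")
  expect_equal(std$data$a, c(-1, 0, 1))
  expect_false("k" %in% names(std$data))   # constant column dropped
  expect_lt(abs(mean(std$data$b)), 1e-9)
  expect_equal(sd(std$data$b), 1, tolerance = 1e-12)
  # the scaler projects new data with the training constants
  new <- predict(std$scaler, tibble::tibble(a = 4, b = 20))
  expect_equal(new$a, (4 - 2) / 1)
})

test_that("PCA retains the threshold-determined component count", {
  # rank one: all variance along a single direction
  set.seed(4)
  t1 <- rnorm(20)
  rank1 <- tibble::tibble(x = t1, y = 2 * t1, z = -t1)
  p1 <- fit_pca(rank1, threshold = 0.95)
  expect_equal(p1$k, 1L)
  # exact 0.90 / 0.10 split across two orthogonal directions -> k = 2
  c1 <- rep(c(-3, 3), 10)
  c2 <- rep(c(-1, -1, 1, 1), 5)
  p2 <- fit_pca(tibble::tibble(u = c1, v = c2), threshold = 0.95)
  expect_equal(p2$explained, c(0.9, 0.1))
  expect_equal(p2$k, 2L)
})

test_that("PCA loadings are orthonormal, scores uncorrelated, reconstruction exact", {
  set.seed(9)
  X <- tibble::as_tibble(as.data.frame(matrix(rnorm(40 * 6), 40,
                                              dimnames = list(NULL, paste0("v", 1:6)))))
  p <- fit_pca(X, threshold = 0.95)
  L <- p$loadings
  expect_lt(max(abs(crossprod(L) - diag(ncol(L)))), 1e-8)
  full <- as.matrix(predict(p, X, k = ncol(L)))
  cors <- cor(full)
  expect_lt(max(abs(cors[upper.tri(cors)])), 1e-8)
  # reconstruction from all components
  Xc <- scale(as.matrix(X), center = TRUE, scale = FALSE)
  recon <- (Xc %*% L) %*% t(L)
  expect_lt(max(abs(recon - Xc)), 1e-8)
  # determinism with the sign convention
  p2 <- fit_pca(X, threshold = 0.95)
  expect_identical(p$loadings, p2$loadings)
  expect_true(all(apply(L, 2, function(cl) cl[which.max(abs(cl))] > 0)))
})

test_that("selection-standardization-PCA pipeline is deterministic bit-for-bit", {
  set.seed(22)
  n <- 24
  labels <- rep(c("positive", "negative"), each = n / 2)
  feats <- as.data.frame(matrix(rnorm(n * 30), n,
                                dimnames = list(NULL, paste0("f", 1:30))))
  feats$f1 <- feats$f1 + (labels == "positive") * 3
  feats$f2 <- feats$f2 + (labels == "positive") * 2
  tbl <- dplyr::bind_cols(tibble::tibble(braf_status = labels), feats)
  run_once <- function() {
    rep1 <- select_features(tbl, features = paste0("f", 1:30))
    std <- standardize_features(tbl, attr(rep1, "selected"))
    pca <- fit_pca(std$data, threshold = 0.95)
    predict(pca, std$data)
  }
  expect_identical(run_once(), run_once())
})
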
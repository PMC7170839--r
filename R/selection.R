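#' One-sample Kolmogorov-Smirnov normality check
#'
#' Z-scores the values and tests them against the standard normal. Verdict is
#' `"non-normal"` when p < alpha, and also — with a sentinel `NA` p-value —
#' when fewer than 3 finite values or zero spread make the test undefined.
#'
#' @param values Numeric vector.
#' @param alpha Significance level for the verdict (default 0.05).
#' @return List with `verdict` (`"normal"` / `"non-normal"`) and `p`.
#' @export
test_normality <- function(values, alpha = 0.05) {
  x <- values[is.finite(values)]
  if (length(x) < 3L || sd(x) == 0) {
    return(list(verdict = "non-normal", p = NA_real_))
  }
  z <- (x - mean(x)) / sd(x)
  p <- suppressWarnings(ks.test(z, "pnorm")$p.value)
  list(verdict = if (p < alpha) "non-normal" else "normal", p = p)
}

#' Distribution-gated two-group difference test
#'
#' Pooled-variance two-sample t-test when both groups pass the KS normality
#' check, otherwise the Mann-Whitney U test (normal approximation with tie
#' correction). Two-sided throughout. Degenerate groups (too few values or
#' zero spread) fall to the Mann-Whitney branch.
#'
#' @param values_pos,values_neg Numeric vectors, each with >= 2 values.
#' @return List with `p`, `test` (`"t"` / `"mann_whitney"`), and the two
#'   normality verdicts.
#' @export
group_difference_test <- function(values_pos, values_neg) {
  if (length(values_pos) < 2L || length(values_neg) < 2L) {
    abort("Both groups need at least 2 values.", class = "radbiopsy_bad_groups")
  }
  np <- test_normality(values_pos)
  nn <- test_normality(values_neg)
  if (np$verdict == "normal" && nn$verdict == "normal") {
    p <- t.test(values_pos, values_neg, var.equal = TRUE)$p.value
    test <- "t"
  } else {
    p <- suppressWarnings(
      wilcox.test(values_pos, values_neg, exact = FALSE, correct = TRUE)$p.value
    )
    test <- "mann_whitney"
  }
  list(p = p, test = test, normal_pos = np$verdict, normal_neg = nn$verdict)
}

#' Univariate screening of features between BRAF classes
#'
#' Applies [group_difference_test()] to every feature column and selects those
#' with p below `alpha`. Features carrying non-finite values (e.g. texture
#' sentinels for lesions thinner than the co-occurrence displacement) are
#' reported with test `"undefined"`, a missing p-value, and are never
#' selected. No multiplicity correction is applied by default
#' (`adjust = "none"`), replicating the original analysis; set `adjust = "BH"`
#' for a Benjamini-Hochberg variant.
#'
#' @param data Tibble with a class column and feature columns.
#' @param features Character vector of feature column names (default: all
#'   columns of [feature_names()] present in `data`).
#' @param class_col Name of the binary class column (values
#'   `positive`/`negative`).
#' @param alpha Selection threshold on the (possibly adjusted) p-value.
#' @param adjust `"none"` (default) or any [stats::p.adjust()] method.
#' @return A `selection_report`: tibble (feature, normal_pos, normal_neg,
#'   test, p, p_adjusted, selected) with attributes `alpha`, `adjust`,
#'   `selected` (character vector).
#' @export
select_features <- function(data, features = NULL, class_col = "braf_status",
                            alpha = 0.05, adjust = "none") {
  stopifnot(is.data.frame(data))
  labels <- as_binary_label(data[[class_col]])
  if (dplyr::n_distinct(labels) < 2L) {
    abort("Both classes must be present for feature selection.",
          class = "radbiopsy_single_class")
  }
  if (is.null(features)) {
    features <- intersect(feature_names(), names(data))
    if (length(features) == 0L) features <- setdiff(names(data), class_col)
  }
  pos <- labels == "positive"
  rows <- purrr::map(features, function(f) {
    x <- data[[f]]
    if (any(!is.finite(x))) {
      # e.g. GLCM sentinels for lesions thinner than the displacement
      return(tibble(feature = f, normal_pos = NA_character_,
                    normal_neg = NA_character_, test = "undefined",
                    p = NA_real_))
    }
    r <- group_difference_test(x[pos], x[!pos])
    tibble(feature = f, normal_pos = r$normal_pos, normal_neg = r$normal_neg,
           test = r$test, p = r$p)
  })
  rep_tbl <- dplyr::bind_rows(rows)
  rep_tbl$p_adjusted <- stats::p.adjust(rep_tbl$p, method = adjust)
  rep_tbl$selected <- !is.na(rep_tbl$p_adjusted) & rep_tbl$p_adjusted < alpha
  structure(rep_tbl,
            class = c("selection_report", class(rep_tbl)),
            alpha = alpha, adjust = adjust,
            selected = rep_tbl$feature[rep_tbl$selected])
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report> ", sum(x$selected), " of ", nrow(x),
      " features selected at alpha = ", attr(x, "alpha"),
      " (adjust = ", attr(x, "adjust"), ")\n", sep = "")
  NextMethod()
}

#' @export
tidy.selection_report <- function(x, ...) {
  as_tibble(unclass(x)[c("feature", "normal_pos", "normal_neg",
                         "test", "p", "p_adjusted", "selected")])
}

#' @export
glance.selection_report <- function(x, ...) {
  tibble(n_features = nrow(x), n_selected = sum(x$selected),
         n_t_test = sum(x$test == "t"),
         n_mann_whitney = sum(x$test == "mann_whitney"),
         n_undefined = sum(x$test == "undefined"),
         alpha = attr(x, "alpha"), adjust = attr(x, "adjust"))
}

#' Fit cohort-level standardization constants
#'
#' Per feature: subtract the cohort mean, divide by the cohort sample SD
#' (divisor n - 1), so every standardized column has mean 0 and unit sample
#' SD. Zero-spread features are dropped with a warning (they carry no
#' information and break the division).
#'
#' @param data Tibble holding the feature columns.
#' @param features Feature column names to standardize.
#' @return A `feature_scaler` with `constants` (tibble: feature, mean, sd).
#' @export
fit_scaler <- function(data, features) {
  mu <- unname(vapply(features, function(f) mean(data[[f]]), numeric(1)))
  s <- unname(vapply(features, function(f) sd(data[[f]]), numeric(1)))
  drop <- !is.finite(s) | s == 0
  if (any(drop)) {
    warn(paste0("Dropping ", sum(drop), " zero-spread feature(s): ",
                paste(head(features[drop], 5), collapse = ", ")))
  }
  structure(
    list(constants = tibble(feature = features[!drop],
                            mean = mu[!drop], sd = s[!drop])),
    class = "feature_scaler"
  )
}

#' Apply a fitted standardization
#'
#' @param object A `feature_scaler`.
#' @param data Tibble containing the scaler's feature columns.
#' @param ... Unused.
#' @return Tibble of the standardized feature columns only.
#' @export
predict.feature_scaler <- function(object, data, ...) {
  k <- object$constants
  out <- lapply(seq_len(nrow(k)), function(i) {
    (data[[k$feature[i]]] - k$mean[i]) / k$sd[i]
  })
  names(out) <- k$feature
  as_tibble(out)
}

#' Standardize feature columns in one step
#'
#' Convenience wrapper: [fit_scaler()] then [predict()] on the same data.
#'
#' @inheritParams fit_scaler
#' @return List with `data` (standardized tibble) and `scaler`.
#' @export
standardize_features <- function(data, features) {
  sc <- fit_scaler(data, features)
  list(data = predict(sc, data), scaler = sc)
}

#' Principal component analysis with a variance threshold
#'
#' Eigendecomposition of the feature covariance of the (already standardized)
#' selected features. Retains the smallest number of components whose
#' cumulative explained variance reaches `threshold`; eigenvalues below
#' `1e-12` of the total are discarded as numerical rank deficiency. Component
#' signs are fixed by making each component's largest-magnitude loading
#' positive, so refits are bit-reproducible.
#'
#' @param data Tibble of standardized feature columns (>= 2 features, >= 3
#'   rows).
#' @param threshold Cumulative explained-variance target in (0, 1].
#' @return A `pca_transform`: `loadings` (features x retained components),
#'   `explained` (variance fractions), `k` (components kept at the
#'   threshold), `threshold`, `features`.
#' @export
fit_pca <- function(data, threshold = 0.95) {
  X <- as.matrix(data)
  if (ncol(X) < 2L || nrow(X) < 3L) {
    abort("PCA needs >= 2 features and >= 3 lesions.", class = "radbiopsy_bad_pca")
  }
  ev <- eigen(cov(X), symmetric = TRUE)
  keep <- ev$values > 1e-12 * sum(pmax(ev$values, 0))
  vals <- ev$values[keep]
  vecs <- ev$vectors[, keep, drop = FALSE]
  # sign convention: largest-|loading| entry positive
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  explained <- vals / sum(vals)
  k <- which(cumsum(explained) >= threshold - 1e-12)[1]
  rownames(vecs) <- colnames(X)
  colnames(vecs) <- paste0("pc", seq_len(ncol(vecs)))
  structure(
    list(loadings = vecs, explained = explained, k = as.integer(k),
         threshold = threshold, features = colnames(X)),
    class = "pca_transform"
  )
}

#' @export
print.pca_transform <- function(x, ...) {
  cat("<pca_transform> ", length(x$features), " features -> ", x$k,
      " components (", round(100 * sum(x$explained[seq_len(x$k)]), 1),
      "% of variance at threshold ", x$threshold, ")\n", sep = "")
  invisible(x)
}

#' Project data onto the retained principal components
#'
#' @param object A `pca_transform`.
#' @param data Tibble containing the transform's (standardized) feature
#'   columns.
#' @param k Number of components (default: the threshold-chosen `object$k`).
#' @param ... Unused.
#' @return Tibble of scores `pc1..pck`.
#' @export
predict.pca_transform <- function(object, data, k = NULL, ...) {
  if (is.null(k)) k <- object$k
  X <- as.matrix(data[, object$features, drop = FALSE])
  S <- X %*% object$loadings[, seq_len(k), drop = FALSE]
  as_tibble(as.data.frame(S))
}

#' @export
tidy.pca_transform <- function(x, ...) {
  tibble(component = paste0("pc", seq_along(x$explained)),
         explained_variance = x$explained,
         cumulative_variance = cumsum(x$explained),
         retained = seq_along(x$explained) <= x$k)
}

#' @export
glance.pca_transform <- function(x, ...) {
  tibble(n_features = length(x$features), k = x$k,
         threshold = x$threshold,
         cumulative_variance_k = sum(x$explained[seq_len(x$k)]))
}
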
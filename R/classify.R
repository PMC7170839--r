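#' Specify one of the six SVM kernel variants
#'
#' The closed kernel set: `linear`, `quadratic`, `cubic` (polynomial degrees
#' 2/3 with unit coefficient), and `fine_gaussian` / `medium_gaussian` /
#' `coarse_gaussian` — radial kernels whose scale follows the conventional
#' fine/medium/coarse rule `sqrt(P)/4`, `sqrt(P)`, `4 sqrt(P)` for `P` input
#' dimensions (resolved at fit time when `scale` is `NULL`).
#'
#' @param name Kernel name.
#' @param cost Soft-margin box constraint (default 1).
#' @param scale Gaussian kernel scale; `NULL` = the per-name convention.
#' @return A `kernel_spec`.
#' @export
kernel_spec <- function(name = c("linear", "quadratic", "cubic",
                                 "fine_gaussian", "medium_gaussian",
                                 "coarse_gaussian"),
                        cost = 1, scale = NULL) {
  name <- match.arg(name)
  if (!is.null(scale) && scale <= 0) {
    abort("Kernel scale must be > 0.", class = "radbiopsy_bad_kernel")
  }
  structure(list(name = name, cost = cost, scale = scale),
            class = "kernel_spec")
}

#' All six kernel variants with default settings
#' @return Named list of [kernel_spec()] objects.
#' @export
svm_kernels <- function() {
  nm <- c("linear", "quadratic", "cubic",
          "fine_gaussian", "medium_gaussian", "coarse_gaussian")
  setNames(lapply(nm, kernel_spec), nm)
}

resolve_kernel <- function(kernel, p_dims) {
  base <- sqrt(p_dims)
  switch(kernel$name,
    linear = list(kernel = "linear", degree = 3, gamma = 1, coef0 = 0),
    quadratic = list(kernel = "polynomial", degree = 2, gamma = 1, coef0 = 1),
    cubic = list(kernel = "polynomial", degree = 3, gamma = 1, coef0 = 1),
    fine_gaussian = {
      s <- if (is.null(kernel$scale)) base / 4 else kernel$scale
      list(kernel = "radial", degree = 3, gamma = 1 / s^2, coef0 = 0)
    },
    medium_gaussian = {
      s <- if (is.null(kernel$scale)) base else kernel$scale
      list(kernel = "radial", degree = 3, gamma = 1 / s^2, coef0 = 0)
    },
    coarse_gaussian = {
      s <- if (is.null(kernel$scale)) 4 * base else kernel$scale
      list(kernel = "radial", degree = 3, gamma = 1 / s^2, coef0 = 0)
    }
  )
}

#' Fit a soft-margin SVM and score held-out lesions
#'
#' Trains on the given scores/labels and returns, for the test rows, signed
#' decision values oriented so positive values favour the BRAF-positive class,
#' plus the 0-thresholded predicted labels. No internal scaling is applied
#' (inputs are already standardized/PCA scores), so results are deterministic.
#'
#' @param train_x,test_x Data frames or matrices of predictor columns.
#' @param train_y Training labels (`positive`/`negative`), both present.
#' @param kernel A [kernel_spec()].
#' @return Tibble with `decision_value` and `predicted` for each test row.
#' @export
train_and_score <- function(train_x, train_y, test_x, kernel = kernel_spec()) {
  train_y <- as_binary_label(train_y)
  if (dplyr::n_distinct(train_y) < 2L) {
    abort("Training fold contains a single class; cannot fit an SVM.",
          class = "radbiopsy_single_class")
  }
  pars <- resolve_kernel(kernel, ncol(as.matrix(train_x)))
  fit <- e1071::svm(as.matrix(train_x), train_y, type = "C-classification",
                    kernel = pars$kernel, degree = pars$degree,
                    gamma = pars$gamma, coef0 = pars$coef0,
                    cost = kernel$cost, scale = FALSE)
  pred <- predict(fit, as.matrix(test_x), decision.values = TRUE)
  dv <- attr(pred, "decision.values")[, 1]
  # e1071 names the decision column "<first>/<second>"; orient to positive
  if (!startsWith(colnames(attr(pred, "decision.values"))[1], "positive")) {
    dv <- -dv
  }
  tibble(decision_value = as.numeric(dv),
         predicted = factor(ifelse(dv > 0, "positive", "negative"),
                            levels = c("negative", "positive")))
}

#' Patient-grouped, class-stratified k-fold assignment
#'
#' Patients (not lesions) are shuffled with the seed and dealt to folds
#' class-by-class, always to the currently least-loaded fold, so that (a) all
#' lesions of one patient share a fold, (b) each class appears in every fold
#' whenever feasible, and (c) fold sizes differ by at most one patient.
#'
#' @param labels Per-lesion class labels (`positive`/`negative`).
#' @param groups Per-lesion patient identifiers.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the patient shuffle.
#' @return Tibble: `lesion` (row index), `group`, `label`, `fold`.
#' @export
make_folds <- function(labels, groups, k = 5L, seed = 1L) {
  labels <- as_binary_label(labels)
  if (dplyr::n_distinct(labels) < 2L) {
    abort("Both classes must be present.", class = "radbiopsy_single_class")
  }
  groups <- as.character(groups)
  patients <- tibble(group = groups, label = labels) |>
    dplyr::distinct(.data$group, .keep_all = TRUE)
  if (nrow(patients) < k) {
    abort(paste0("Fewer patients (", nrow(patients), ") than folds (", k, ")."),
          class = "radbiopsy_too_few_patients")
  }
  fold_of <- integer(0)
  load <- rep(0L, k)
  with_rng_seed(seed, {
    for (cl in c("positive", "negative")) {
      idx <- which(patients$label == cl)
      idx <- idx[sample.int(length(idx))]
      for (i in idx) {
        f <- which.min(load)      # first least-loaded fold
        fold_of[patients$group[i]] <- f
        load[f] <- load[f] + 1L
      }
    }
  })
  tibble(lesion = seq_along(groups), group = groups,
         label = labels, fold = as.integer(fold_of[groups]))
}

#' Per-fold confusion metrics for both classes
#'
#' With BRAF-positive as the reference class (counts TP/FP/TN/FN): per-class
#' precision `TP/(TP+FP)`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`; the classes swap roles for the negative-class block, so the
#' negative class's sensitivity equals the positive class's specificity.
#' An undefined precision (no predictions for the class) is reported as 0
#' with a warning and flagged in `precision_defined_*`.
#'
#' @param predicted,truth Equal-length binary label vectors.
#' @return One-row tibble of per-class metrics, accuracy and the confusion
#'   counts.
#' @export
evaluate_fold <- function(predicted, truth) {
  predicted <- as_binary_label(predicted)
  truth <- as_binary_label(truth)
  if (length(predicted) == 0L || length(predicted) != length(truth)) {
    abort("predicted and truth must be nonempty and equal length.",
          class = "radbiopsy_bad_input")
  }
  tp <- sum(predicted == "positive" & truth == "positive")
  fp <- sum(predicted == "positive" & truth == "negative")
  tn <- sum(predicted == "negative" & truth == "negative")
  fn <- sum(predicted == "negative" & truth == "positive")
  prec <- function(num, den, cls) {
    if (den == 0) {
      warn(paste0("No lesions predicted ", cls, "; precision undefined, reported as 0."))
      0
    } else num / den
  }
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  tibble(
    precision_pos = prec(tp, tp + fp, "positive"),
    sensitivity_pos = rate(tp, tp + fn),
    specificity_pos = rate(tn, tn + fp),
    precision_neg = prec(tn, tn + fn, "negative"),
    sensitivity_neg = rate(tn, tn + fp),
    specificity_neg = rate(tp, tp + fn),
    accuracy = (tp + tn) / length(truth),
    tp = tp, fp = fp, tn = tn, fn = fn,
    precision_defined_pos = tp + fp > 0,
    precision_defined_neg = tn + fn > 0
  )
}

#' ROC curve and AUC from decision values
#'
#' Threshold sweep over the unique decision values gives the ROC step curve
#' from (0,0) to (1,1); the AUC is the Mann-Whitney pairwise ranking
#' statistic normalized by `n_pos * n_neg`, with ties contributing 0.5
#' (computed via midranks, and identical to trapezoidal integration of the
#' tie-grouped sweep).
#'
#' @param decision_values Numeric scores, larger = more BRAF-positive.
#' @param truth Binary labels, both classes present.
#' @return A `roc_result`: `points` (tibble threshold/fpr/tpr) and `auc`.
#' @export
roc_auc <- function(decision_values, truth) {
  truth <- as_binary_label(truth)
  if (dplyr::n_distinct(truth) < 2L) {
    abort("Both classes must be present in `truth`.",
          class = "radbiopsy_single_class")
  }
  pos <- truth == "positive"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  r <- rank(decision_values)          # midranks handle ties as 0.5
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(decision_values), decreasing = TRUE)
  pts <- tibble(
    threshold = c(Inf, thr),
    tpr = c(0, vapply(thr, function(t) sum(pos & decision_values >= t), numeric(1)) / n_pos),
    fpr = c(0, vapply(thr, function(t) sum(!pos & decision_values >= t), numeric(1)) / n_neg)
  )
  structure(list(points = pts, auc = auc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> AUC = ", round(x$auc, 4), " over ",
      nrow(x$points) - 1L, " thresholds\n", sep = "")
  invisible(x)
}

#' Summarize fold metrics into a cross-validation report
#'
#' Means and population SDs (divisor = number of folds) of every per-fold
#' metric, the pooled confusion matrix, and the ROC/AUC over the pooled
#' validation-fold decision values (per-fold AUCs are kept alongside).
#'
#' @param fold_metrics Tibble of [evaluate_fold()] rows (>= 2 folds).
#' @param pooled Optional tibble with `decision_value` and `truth` pooled
#'   over validation folds (adds ROC/AUC to the report).
#' @param kernel,mode,seed Metadata recorded in the report.
#' @return A `cv_report`.
#' @export
summarize_cv <- function(fold_metrics, pooled = NULL, kernel = NULL,
                         mode = "cohort_fit", seed = NA_integer_) {
  if (nrow(fold_metrics) < 2L) {
    abort("Need >= 2 folds to summarize.", class = "radbiopsy_bad_input")
  }
  metric_cols <- c("precision_pos", "sensitivity_pos", "specificity_pos",
                   "precision_neg", "sensitivity_neg", "specificity_neg",
                   "accuracy")
  summary <- dplyr::bind_rows(lapply(metric_cols, function(mcol) {
    v <- fold_metrics[[mcol]]
    tibble(metric = mcol, mean = mean(v), sd = sd_pop(v))
  }))
  confusion <- NULL
  if (all(c("tp", "fp", "tn", "fn") %in% names(fold_metrics))) {
    confusion <- matrix(
      c(sum(fold_metrics$tp), sum(fold_metrics$fn),
        sum(fold_metrics$fp), sum(fold_metrics$tn)),
      2, 2,
      dimnames = list(predicted = c("positive", "negative"),
                      truth = c("positive", "negative"))
    )
  }
  roc <- NULL; auc <- NA_real_
  if (!is.null(pooled)) {
    roc <- roc_auc(pooled$decision_value, pooled$truth)
    auc <- roc$auc
  }
  structure(
    list(fold_metrics = fold_metrics, summary = summary,
         confusion = confusion, roc = roc, auc = auc,
         kernel = if (is.null(kernel)) NA_character_ else kernel$name,
         mode = mode, seed = seed),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> kernel = ", x$kernel, ", mode = ", x$mode,
      ", folds = ", nrow(x$fold_metrics), "\n", sep = "")
  acc <- x$summary[x$summary$metric == "accuracy", ]
  cat(sprintf("  mean accuracy %.2f +- %.2f; pooled AUC %s\n",
              acc$mean, acc$sd,
              if (is.na(x$auc)) "n/a" else sprintf("%.2f", x$auc)))
  invisible(x)
}

#' @export
tidy.cv_report <- function(x, ...) x$summary

#' @export
glance.cv_report <- function(x, ...) {
  acc <- x$summary[x$summary$metric == "accuracy", ]
  tibble(kernel = x$kernel, mode = x$mode, n_folds = nrow(x$fold_metrics),
         mean_accuracy = acc$mean, sd_accuracy = acc$sd, auc = x$auc,
         seed = x$seed)
}

#' Cross-validate one SVM kernel on a score table
#'
#' Runs patient-grouped stratified k-fold cross-validation of
#' [train_and_score()], collecting per-fold metrics and pooled decision
#' values.
#'
#' @param scores Tibble/data frame of predictor columns (PCA scores).
#' @param labels Per-lesion class labels.
#' @param groups Per-lesion patient identifiers.
#' @param kernel A [kernel_spec()].
#' @param k Number of folds.
#' @param seed Seed for the fold shuffle.
#' @param mode Label recorded in the report.
#' @return A `cv_report`.
#' @export
cross_validate_svm <- function(scores, labels, groups, kernel = kernel_spec(),
                               k = 5L, seed = 1L, mode = "cohort_fit") {
  folds <- make_folds(labels, groups, k = k, seed = seed)
  labels <- as_binary_label(labels)
  per_fold <- vector("list", k)
  pooled <- vector("list", k)
  for (f in seq_len(k)) {
    te <- folds$fold == f
    sc <- train_and_score(scores[!te, , drop = FALSE], labels[!te],
                          scores[te, , drop = FALSE], kernel)
    per_fold[[f]] <- evaluate_fold(sc$predicted, labels[te])
    per_fold[[f]]$fold_auc <- tryCatch(
      roc_auc(sc$decision_value, labels[te])$auc,
      error = function(e) NA_real_
    )
    pooled[[f]] <- tibble(decision_value = sc$decision_value,
                          truth = labels[te])
  }
  summarize_cv(dplyr::bind_rows(per_fold), dplyr::bind_rows(pooled),
               kernel = kernel, mode = mode, seed = seed)
}
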
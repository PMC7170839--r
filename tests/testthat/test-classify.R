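test_that("folds are patient-grouped, stratified, and balanced", {
  # 10 lesions, one per patient, 5 per class -> one lesion per class per fold
  lab <- rep(c("positive", "negative"), each = 5)
  grp <- paste0("p", 1:10)
  f <- make_folds(lab, grp, k = 5, seed = 3)
  per_fold <- table(f$fold, f$label)
  expect_true(all(per_fold == 1))
  # a two-lesion patient stays in one fold
  lab2 <- c(lab, "negative")
  grp2 <- c(grp, "p10")
  f2 <- make_folds(lab2, grp2, k = 5, seed = 3)
  expect_equal(dplyr::n_distinct(f2$fold[f2$group == "p10"]), 1L)
  # 53 patients over 5 folds -> patient counts {11, 11, 11, 10, 10}
  lab3 <- rep(c("positive", "negative"), c(25, 28))
  grp3 <- paste0("q", 1:53)
  f3 <- make_folds(lab3, grp3, k = 5, seed = 1)
  sizes <- as.integer(table(f3$fold))
  expect_equal(sort(sizes), c(10L, 10L, 11L, 11L, 11L))
  expect_true(all(table(f3$fold, f3$label) > 0))
  # deterministic under a fixed seed
  expect_identical(f3, make_folds(lab3, grp3, k = 5, seed = 1))
  expect_error(make_folds(c("positive", "negative"), c("a", "b"), k = 5),
               class = "radbiopsy_too_few_patients")
})

test_that("SVM training separates separable data and gaussians solve XOR", {
  set.seed(6)
  x <- rbind(matrix(rnorm(40, 3), 20), matrix(rnorm(40, -3), 20))
  y <- rep(c("positive", "negative"), each = 20)
  sc <- train_and_score(x, y, x, kernel_spec("linear"))
  expect_equal(mean(sc$predicted == y), 1.0)
  expect_true(all(sc$decision_value[1:20] > 0))  # oriented to positive class
  # XOR: linear fails, fine gaussian memorizes
  xor_x <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4, 2)
  xor_y <- c("positive", "negative", "negative", "positive")
  lin <- train_and_score(xor_x, xor_y, xor_x, kernel_spec("linear"))
  expect_lte(mean(lin$predicted == xor_y), 0.75)
  fg <- train_and_score(xor_x, xor_y, xor_x, kernel_spec("fine_gaussian"))
  expect_equal(mean(fg$predicted == xor_y), 1.0)
  expect_error(train_and_score(x, rep("positive", 40), x),
               class = "radbiopsy_single_class")
})

test_that("train accuracy is at least the majority-class baseline", {
  set.seed(8)
  x <- matrix(rnorm(60), 30, 2)
  y <- rep(c("positive", "negative"), c(18, 12))
  for (kn in names(svm_kernels())) {
    sc <- train_and_score(x, y, x, svm_kernels()[[kn]])
    expect_gte(mean(sc$predicted == y), 18 / 30)
  }
})

test_that("fold metrics reproduce direct confusion counting", {
  perfect <- evaluate_fold(rep(c("positive", "negative"), 5),
                           rep(c("positive", "negative"), 5))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$precision_pos, 1)
  expect_equal(perfect$sensitivity_neg, 1)
  # TP=2 FN=3 TN=5 FP=1
  truth <- c(rep("positive", 5), rep("negative", 6))
  pred <- c("positive", "positive", "negative", "negative", "negative",
            "positive", rep("negative", 5))
  m <- evaluate_fold(pred, truth)
  expect_equal(m$sensitivity_pos, 0.40)
  expect_equal(m$precision_pos, 2 / 3)
  expect_equal(m$specificity_pos, 5 / 6)
  expect_equal(m$sensitivity_neg, m$specificity_pos)   # role swap
  expect_equal(m$specificity_neg, m$sensitivity_pos)
  expect_equal(m$accuracy, 7 / 11)
  # all predicted positive: positive precision = prevalence, negative 0 + warning
  expect_warning(deg <- evaluate_fold(rep("positive", 11), truth), "undefined")
  expect_equal(deg$precision_pos, 5 / 11)
  expect_equal(deg$precision_neg, 0)
  expect_false(deg$precision_defined_neg)
  expect_error(evaluate_fold(character(0), character(0)),
               class = "radbiopsy_bad_input")
})

test_that("summarize_cv reproduces the published fold-metric arithmetic", {
  ref <- reference_fold_metrics()
  rep_cv <- summarize_cv(ref, kernel = kernel_spec("linear"))
  s <- rep_cv$summary
  get <- function(metric, col) s[[col]][s$metric == metric]
  expect_equal(round(get("precision_pos", "mean"), 2), 0.77)
  expect_equal(round(get("sensitivity_pos", "mean"), 2), 0.72)
  expect_equal(round(get("specificity_pos", "mean"), 2), 0.83)
  expect_equal(round(get("precision_neg", "mean"), 2), 0.79)
  expect_equal(round(get("sensitivity_pos", "sd"), 2), 0.20)  # population SD
  # summary mean equals the arithmetic fold mean to machine precision
  expect_lt(abs(get("accuracy", "mean") - mean(ref$accuracy)), 1e-12)
  # identical folds give SD 0
  const <- ref[rep(1, 3), ]
  s0 <- summarize_cv(const)$summary
  expect_true(all(s0$sd == 0))
  expect_error(summarize_cv(ref[1, ]), class = "radbiopsy_bad_input")
})

test_that("ROC/AUC follows the tie-aware pairwise ranking convention", {
  perfect <- roc_auc(c(5, 4, 3, 1, 0), c("positive", "positive", "positive",
                                         "negative", "negative"))
  expect_equal(perfect$auc, 1.0)
  ties <- roc_auc(rep(1, 6), rep(c("positive", "negative"), 3))
  expect_equal(ties$auc, 0.5)
  ex <- roc_auc(c(0.9, 0.8, 0.4, 0.7, 0.3),
                c("positive", "positive", "positive", "negative", "negative"))
  expect_equal(ex$auc, 5 / 6)
  expect_error(roc_auc(1:3, rep("positive", 3)),
               class = "radbiopsy_single_class")
})

test_that("ROC curves are monotone step curves from (0,0) to (1,1)", {
  set.seed(10)
  r <- roc_auc(rnorm(30), sample(c("positive", "negative"), 30, TRUE,
                                 prob = c(0.4, 0.6)))
  pts <- r$points
  expect_equal(pts$fpr[1], 0); expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1); expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
  # trapezoid over the step curve equals the rank-based AUC
  trap <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + diff(pts$tpr) / 2))
  expect_equal(trap, r$auc, tolerance = 1e-12)
})

test_that("AUC equals exhaustive pair comparison and the pROC reference", {
  skip_if_not_installed("pROC")
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(8:20, 1)
    truth <- c("positive", "negative",
               sample(c("positive", "negative"), n - 2, TRUE))
    scores <- round(rnorm(n), 1)   # rounding forces ties
    got <- roc_auc(scores, truth)$auc
    expect_identical(got, auc_oracle(scores, truth))
    proc <- suppressMessages(pROC::auc(pROC::roc(
      response = truth, predictor = scores, levels = c("negative", "positive"),
      direction = "<", quiet = TRUE)))
    expect_equal(got, as.numeric(proc), tolerance = 1e-12)
  }
})

test_that("cross_validate_svm produces a coherent report on an easy problem", {
  set.seed(14)
  n <- 40
  labels <- rep(c("positive", "negative"), each = n / 2)
  scores <- tibble::tibble(pc1 = rnorm(n) + 4 * (labels == "positive"),
                           pc2 = rnorm(n))
  cv <- cross_validate_svm(scores, labels, paste0("p", 1:n),
                           kernel_spec("linear"), k = 5, seed = 2)
  expect_s3_class(cv, "cv_report")
  expect_equal(nrow(cv$fold_metrics), 5L)
  expect_gt(cv$auc, 0.9)
  expect_equal(sum(cv$confusion), n)
  expect_equal(glance(cv)$kernel, "linear")
  # negative-class sensitivity equals positive specificity fold by fold
  expect_equal(cv$fold_metrics$sensitivity_neg, cv$fold_metrics$specificity_pos)
})
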
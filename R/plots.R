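#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(linewidth = 0.8, colour = "#2c7fb8") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC (AUC = %.2f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cv_report <- function(object, ...) {
  if (is.null(object$roc)) {
    abort("This cv_report has no pooled ROC to plot.",
          class = "radbiopsy_no_roc")
  }
  autoplot(object$roc) +
    ggplot2::labs(subtitle = paste0("kernel: ", object$kernel,
                                    ", mode: ", object$mode))
}

#' @export
autoplot.pca_transform <- function(object, ...) {
  df <- tidy(object)
  df$idx <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$idx, y = .data$cumulative_variance)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$explained_variance),
                      fill = "grey75") +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$retained), size = 2) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2c7fb8",
                                            `FALSE` = "grey50")) +
    ggplot2::labs(x = "Component", y = "Variance fraction",
                  colour = "Retained",
                  title = sprintf("%d components reach %.0f%% of variance",
                                  object$k, 100 * object$threshold)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.selection_report <- function(object, ...) {
  df <- tidy(object)
  df$family <- sub("\\..*$", "", df$feature)
  df$idx <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$idx, y = -log10(.data$p),
                                   colour = .data$family,
                                   shape = .data$selected)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "alpha")),
                        linetype = 2) +
    ggplot2::labs(x = "Feature index", y = expression(-log[10](p)),
                  title = sprintf("%d / %d features below alpha = %.2f",
                                  sum(df$selected), nrow(df),
                                  attr(object, "alpha"))) +
    ggplot2::theme_minimal()
}
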
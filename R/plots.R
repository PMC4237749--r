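#' Plot per-fold cross-validation metrics
#'
#' @param object An `epi_cv` from [cross_validate()].
#' @param ... Unused.
#' @return A ggplot: one boxplot per metric over the fold results.
#' @export
autoplot.epi_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(object$folds, -c(repeat_id, fold),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = metric, y = value)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5, size = 1) +
    ggplot2::labs(x = NULL, y = "per-fold value") +
    ggplot2::theme_minimal()
}

#' Plot a ROC curve
#'
#' @param roc Result of [roc_auc()].
#' @param ... Unused.
#' @return A ggplot of the ROC curve with the chance diagonal.
#' @export
plot_roc <- function(roc, ...) {
  ggplot2::ggplot(roc$points, ggplot2::aes(x = fpr, y = tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(colour = "steelblue") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  subtitle = sprintf("AUC = %.3f", roc$auc)) +
    ggplot2::theme_minimal()
}

#' Plot an ablation trace
#'
#' @param object An `ablation_trace`.
#' @param ... Unused.
#' @return A ggplot of the ablation measure along the removal/addition order.
#' @export
autoplot.ablation_trace <- function(object, ...) {
  tab <- tidy(object)
  tab$classifier <- factor(tab$classifier, levels = tab$classifier)
  ggplot2::ggplot(tab, ggplot2::aes(x = classifier,
                                    y = .data[[object$measure]], group = 1)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(colour = "steelblue", size = 2) +
    ggplot2::labs(x = NULL, y = object$measure) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
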
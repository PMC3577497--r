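# ggplot2 methods for the package's result objects.

#' Plot an ROC curve
#'
#' Sensitivity against 1 - specificity, with the chance diagonal and,
#' optionally, the closest-to-corner optimum highlighted.
#'
#' @param object An [build_roc()] curve.
#' @param mark_optimum Highlight the [optimal_threshold()] point.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lncr_roc <- function(object, mark_optimum = TRUE, ...) {
  df <- tibble(fpr = 1 - object$specificity, tpr = object$sensitivity)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(colour = "steelblue") +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("ROC (AUC = %.4f)", roc_auc(object))) +
    ggplot2::coord_equal()
  if (mark_optimum) {
    opt <- optimal_threshold(object)
    p <- p + ggplot2::annotate("point", x = 1 - opt$specificity,
                               y = opt$sensitivity, colour = "red", size = 2) +
      ggplot2::annotate("text", x = 1 - opt$specificity, y = opt$sensitivity,
                        label = sprintf(" t* = %.3g", opt$optimum_threshold),
                        hjust = 0, vjust = 1, size = 3)
  }
  p
}

#' Plot pipeline retention accounting
#'
#' Retained and filtered transcript counts per pipeline step.
#'
#' @param object An `lncscan_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lncscan_result <- function(object, ...) {
  df <- object$accounting |>
    tidyr::pivot_longer(c("retained", "filtered"), names_to = "outcome",
                        values_to = "count") |>
    mutate(step = factor(.data$step, levels = object$accounting$step))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$count,
                                   fill = .data$outcome)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_manual(values = c(filtered = "grey70",
                                          retained = "steelblue")) +
    ggplot2::labs(x = NULL, y = "transcripts",
                  title = "Per-step retention accounting") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Category composition bar chart
#'
#' @param classification Output of [classify_transcripts()] or a
#'   [categorize_summary()] table.
#' @return A ggplot of transcript counts per class code.
#' @export
plot_categories <- function(classification) {
  tab <- if (all(c("n", "percentage") %in% names(classification))) {
    classification
  } else {
    categorize_summary(classification)
  }
  tab$class_code <- factor(tab$class_code, levels = class_codes())
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$class_code, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "class code", y = "transcripts",
                  title = "Class-code composition")
}
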
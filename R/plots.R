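#' Plot the ROC curve of a fitted classifier
#'
#' @param x An `scd_fit` (pooled validation ROC) or the list returned by
#'   [roc_auc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_roc <- function(x, ...) {
  ra <- if (inherits(x, "scd_fit")) {
    list(roc = x$metrics$roc, auc = x$metrics$auc)
  } else {
    x
  }
  ggplot2::ggplot(ra$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         linetype = "dashed", colour = "red") +
    ggplot2::geom_path(colour = "blue") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False-positive rate", y = "True-positive rate",
      title = sprintf("ROC (AUC = %.5f)", ra$auc)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.scd_fit <- function(object, ...) {
  plot_roc(object, ...)
}

#' Histogram of one parameter with its tail-criterion threshold
#'
#' Visualises the selective search for one morphological parameter:
#' class-coloured histograms with the qualifying threshold marked.
#'
#' @param features Feature table with a `class` column.
#' @param criteria Criteria tibble from [search_all_parameters()].
#' @param parameter Feature name to show.
#' @param bins Histogram bin count.
#' @return A ggplot object.
#' @export
plot_tail_criterion <- function(features, criteria, parameter, bins = 80) {
  stopifnot(parameter %in% names(features))
  crit <- criteria[criteria$parameter == parameter, , drop = FALSE]
  p <- ggplot2::ggplot(
    features,
    ggplot2::aes(x = .data[[parameter]], fill = .data$class)
  ) +
    ggplot2::geom_histogram(alpha = 0.5, bins = bins,
                            position = "identity") +
    ggplot2::labs(x = parameter, y = "cells") +
    ggplot2::theme_minimal()
  if (nrow(crit) > 0) {
    p <- p + ggplot2::geom_vline(
      data = crit,
      ggplot2::aes(xintercept = .data$threshold),
      linetype = "dashed"
    )
  }
  p
}

#' @export
autoplot.tail_criteria <- function(object, features, parameter = NULL, ...) {
  parameter <- parameter %||% object$parameter[1]
  plot_tail_criterion(features, object, parameter, ...)
}

#' Bar chart of per-sample predicted disease percentages
#'
#' @param report A `sample_report` from [evaluate_samples()].
#' @param thresholds Decision thresholds drawn as horizontal lines.
#' @return A ggplot object.
#' @export
plot_sample_report <- function(report, thresholds = decision_thresholds()) {
  ggplot2::ggplot(
    report,
    ggplot2::aes(x = .data$sample_id, y = .data$pct_scd, fill = .data$call)
  ) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = thresholds$lower_bound_pct,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = thresholds$upper_band_pct,
                        linetype = "dotted") +
    ggplot2::labs(x = NULL, y = "predicted % critically sickled") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @export
autoplot.sample_report <- function(object, ...) {
  plot_sample_report(object, ...)
}
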
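#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a ROC curve
#'
#' @param object An `lnc_roc` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lnc_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(colour = "#2166ac", linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC curve (AUC = %.4f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a metrics report as a bar chart
#'
#' @param object An `lnc_metrics` from [compute_metrics()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lnc_metrics <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("sensitivity", "specificity", "precision",
                          "accuracy", "f_score", "mcc"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "Value", title = "Classification metrics") +
    ggplot2::theme_minimal()
}

#' Plot feature importance of a trained model
#'
#' @param model An `lnc_model`.
#' @param top_n Show at most this many features.
#' @return A ggplot of gain importance, most important on top.
#' @export
plot_feature_importance <- function(model, top_n = 30L) {
  df <- head(tidy(model), top_n)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gain,
                                   y = stats::reorder(.data$feature, .data$gain))) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = "Gain", y = NULL, title = "Feature importance") +
    ggplot2::theme_minimal()
}

#' Plot an RFECV accuracy trace
#'
#' @param trace The `trace` tibble from [rfecv_select()] (also stored on
#'   models trained with `rfecv = TRUE`).
#' @return A ggplot of cross-validation accuracy vs subset size.
#' @export
plot_rfecv_trace <- function(trace) {
  best <- trace[order(-trace$cv_accuracy, trace$size), ][1, ]
  ggplot2::ggplot(trace, ggplot2::aes(x = .data$size, y = .data$cv_accuracy)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = best$size, linetype = "dashed",
                        colour = "#b2182b") +
    ggplot2::labs(x = "Number of features", y = "CV accuracy",
                  title = "Recursive feature elimination") +
    ggplot2::theme_minimal()
}
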
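# ggplot2 displays for the result objects.

#' Plot per-participant trip accuracy colored by diagnostic group
#'
#' @param object A `risk_report` with true labels.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.risk_report <- function(object, ...) {
  df <- mutate(object, group = ifelse(.data$label == 1, "MCI", "healthy"))
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$participant_id, -.data$trip_accuracy),
    y = 100 * .data$trip_accuracy, fill = .data$group
  )) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(healthy = "#2e7d32", MCI = "#c62828")) +
    ggplot2::labs(
      x = NULL, y = "correctly classified trips (%)", fill = NULL,
      title = "Per-participant trip classification accuracy"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot sensitivity and specificity across risk thresholds
#'
#' @param object A `threshold_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.threshold_curve <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as_tibble(object), all_of(c("sensitivity", "specificity")),
    names_to = "measure", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$threshold, .data$value, colour = .data$measure)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = c(0.1, 0.5), linetype = "dashed", alpha = 0.4) +
    ggplot2::labs(
      x = "risk-score flagging threshold", y = NULL, colour = NULL,
      title = "Screening trade-off across risk thresholds"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the training loss history of a fitted model
#'
#' @param object An `mcidrive_model` with history.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.mcidrive_model <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "training loss") +
    ggplot2::theme_minimal()
}

#' Plot per-fold metric dispersion of a cross-validation run
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.cv_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$metric, .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = NULL, title = "Per-fold cross-validation metrics") +
    ggplot2::theme_minimal()
}
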
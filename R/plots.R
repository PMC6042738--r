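# ggplot2 views of frames, ROC curves, study grids and the classifier
# comparison table.

#' Plot a measurement frame's channel profile
#'
#' @param frame Numeric vector of channel voltages, or a frame dataset
#'   tibble (each row drawn as one line).
#' @param log_scale Use a log10 voltage axis (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_frame <- function(frame, log_scale = TRUE) {
  if (is.numeric(frame) && is.null(dim(frame))) {
    df <- tibble(frame_id = 1L, channel = seq_along(frame), voltage = as.numeric(frame))
  } else {
    m <- frame_matrix(frame)
    df <- tibble(
      frame_id = rep(seq_len(nrow(m)), each = ncol(m)),
      channel = rep(seq_len(ncol(m)), nrow(m)),
      voltage = as.vector(t(m))
    )
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$channel, .data$voltage,
    group = .data$frame_id
  )) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "channel", y = "voltage magnitude (V)")
  if (log_scale) p <- p + ggplot2::scale_y_log10()
  p
}

#' @describeIn plot_frame Training ROC curve of a classifier.
#' @param object,x Object to plot.
#' @param ... Unused.
#' @method autoplot eit_classifier
#' @export
autoplot.eit_classifier <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf("Training ROC (%s), AUC = %.3f", object$kind, object$auc)
    )
}

#' @describeIn plot_frame Sensitivity/specificity grid of a study result.
#' @method autoplot eit_study_result
#' @export
autoplot.eit_study_result <- function(object, ...) {
  xvar <- if ("test_volume_ml" %in% names(object) &&
    length(unique(object$test_volume_ml)) > 1) {
    "test_volume_ml"
  } else {
    "snr_db"
  }
  long <- tidyr::pivot_longer(as_tibble(object),
    c("sensitivity", "specificity", "accuracy"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data[[xvar]], .data$value,
    colour = .data$metric, linetype = .data$op
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~frames) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      x = if (xvar == "snr_db") "SNR (dB)" else "test lesion volume (ml)",
      y = "rate",
      title = sprintf("Study: %s", attr(object, "study"))
    )
}

#' @describeIn plot_frame Mean +/- sd metrics of a classifier comparison.
#' @method autoplot eit_comparison
#' @export
autoplot.eit_comparison <- function(object, ...) {
  long <- as_tibble(object) |>
    tidyr::pivot_longer(-c("kind", "snr_db"),
      names_to = c("metric", "stat"), names_pattern = "(.*)_(mean|sd)"
    ) |>
    tidyr::pivot_wider(names_from = "stat", values_from = "value")
  ggplot2::ggplot(long, ggplot2::aes(factor(.data$snr_db), .data$mean,
    fill = .data$kind
  )) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$mean - .data$sd, 0),
                   ymax = pmin(.data$mean + .data$sd, 1)),
      position = ggplot2::position_dodge(0.9), width = 0.3
    ) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "SNR (dB)", y = "mean rate (error bar: sd over folds)")
}
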
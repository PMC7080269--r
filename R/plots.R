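#' Plot per-repeat fold accuracies of a cross-validation result
#'
#' Boxplots of fold accuracies per repeat, with the grand mean and the
#' theoretical chance level for the number of classes.
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_result <- function(object, ...) {
  chance <- 100 / length(object$classes)
  ggplot2::ggplot(object$folds,
                  ggplot2::aes(x = factor(.data$repeat_id),
                               y = .data$accuracy)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_hline(yintercept = object$mean, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = chance, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "repeat", y = "fold accuracy (%)",
                  title = sprintf("%s: %.1f +/- %.1f %%", object$mode,
                                  object$mean,
                                  ifelse(is.na(object$sd), 0, object$sd))) +
    ggplot2::theme_minimal()
}

#' Plot a sensor-selection trace
#'
#' For a backward-selection trace, criterion accuracy versus channel count;
#' for an SD-pair search, the best accuracy per pair count. The dashed line
#' marks the 70% effective-BCI threshold.
#'
#' @param object A `selection_result`.
#' @param threshold Effective-BCI threshold to draw (default 70).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.selection_result <- function(object, threshold = 70, ...) {
  tr <- object$trace
  if (object$method == "sd_pair_search") {
    tr <- tr[tr$best_of_size, ]
    x_var <- "n_pairs"; x_lab <- "SD pairs"
  } else if ("size" %in% names(tr)) {
    x_var <- "size"; x_lab <- "EEG channels"
  } else {
    tr$rank <- seq_len(nrow(tr))
    x_var <- "rank"; x_lab <- "candidate rank"
  }
  ggplot2::ggplot(tr, ggplot2::aes(x = .data[[x_var]], y = .data$accuracy)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = x_lab, y = sprintf("%s accuracy (%%)",
                                         paste(object$criterion_pair,
                                               collapse = " vs "))) +
    ggplot2::theme_minimal()
}

#' Plot a study report
#'
#' Per-configuration accuracy distribution across participants.
#'
#' @param object A `study_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.study_report <- function(object, ...) {
  ggplot2::ggplot(object$accuracies,
                  ggplot2::aes(x = .data$configuration, y = .data$accuracy)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = 100 / 3, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = NULL, y = "three-class accuracy (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
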
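#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cross-validation result
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return Tibble with one row per repeat and fold: `repeat_id`, `fold`,
#'   `accuracy` (percent).
#' @export
tidy.cv_result <- function(x, ...) x$folds

#' One-row summary of a cross-validation result
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return Tibble with the mean and standard deviation (across repeat means)
#'   of the accuracy, the CV dimensions and the mode.
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(mean_accuracy = x$mean, sd_accuracy = x$sd,
                 folds = x$cv$folds, repeats = x$cv$repeats,
                 n_trials = x$n_trials, mode = x$mode,
                 n_classes = length(x$classes))
}

#' Tidy a sensor-selection result
#'
#' @param x A `selection_result`.
#' @param ... Unused.
#' @return The search trace as a tibble (one row per evaluated subset or
#'   arrangement, with a readable `channels` label).
#' @export
tidy.selection_result <- function(x, ...) {
  out <- x$trace
  if (is.list(out$channels))
    out$channels_label <- vapply(out$channels, paste, character(1),
                                 collapse = ",")
  out
}

#' Tidy a shrinkage-LDA model
#'
#' @param x An `slda_model`.
#' @param ... Unused.
#' @return Tibble of terms (features plus the bias) and their weights.
#' @export
tidy.slda_model <- function(x, ...) {
  nm <- names(x$w)
  if (is.null(nm)) nm <- paste0("x", seq_along(x$w))
  tibble::tibble(term = c(nm, "(bias)"), estimate = c(unname(x$w), x$b))
}

#' One-row summary of a shrinkage-LDA model
#'
#' @param x An `slda_model`.
#' @param ... Unused.
#' @return Tibble with the shrinkage intensity, target scale and dimensions.
#' @export
glance.slda_model <- function(x, ...) {
  tibble::tibble(gamma = x$gamma, nu = x$nu, n_features = x$p,
                 class1 = x$classes[1], class2 = x$classes[2])
}

#' Tidy a configuration comparison
#'
#' @param x A `config_comparison`.
#' @param ... Unused.
#' @return The pairwise post-hoc table.
#' @export
tidy.config_comparison <- function(x, ...) x$pairwise

#' One-row summary of a configuration comparison (the omnibus test)
#'
#' @param x A `config_comparison`.
#' @param ... Unused.
#' @return Tibble with the Friedman statistic, df and p-value.
#' @export
glance.config_comparison <- function(x, ...) x$omnibus

#' Tidy a study report
#'
#' @param x A `study_report`.
#' @param ... Unused.
#' @return Tibble of per-participant per-configuration accuracies.
#' @export
tidy.study_report <- function(x, ...) x$accuracies

#' Configuration-level summary of a study report
#'
#' @param x A `study_report`.
#' @param ... Unused.
#' @return Tibble with the cross-participant mean and sd per configuration.
#' @export
glance.study_report <- function(x, ...) {
  dplyr::summarise(dplyr::group_by(x$accuracies, .data$configuration),
                   mean_accuracy = mean(.data$accuracy),
                   sd_accuracy = stats::sd(.data$accuracy),
                   n_participants = dplyr::n(), .groups = "drop")
}
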
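#' Plot a learning curve against the ideal-observer bound
#'
#' Line plot of the group mean absolute error per trial with an SEM
#' ribbon, optionally overlaid with the lower bound curve.
#'
#' @param curve A tibble from [learning_curve()].
#' @param bound Optional tibble from [lower_bound()].
#' @return A ggplot object.
#' @export
plot_learning_curve <- function(curve, bound = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("Package `ggplot2` is required for plotting.", call. = FALSE)
  }
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$trial_index,
                                           y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "trial", y = "absolute angular error (deg)") +
    ggplot2::theme_minimal()
  if (!is.null(bound)) {
    p <- p + ggplot2::geom_line(
      data = bound,
      ggplot2::aes(x = .data$trial_index, y = .data$gamma),
      linetype = "dashed"
    )
  }
  p
}

#' Plot group-level Bayesian model weights
#'
#' @param comparison Result of [compare_models()].
#' @return A ggplot object.
#' @export
plot_model_weights <- function(comparison) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("Package `ggplot2` is required for plotting.", call. = FALSE)
  }
  g <- comparison$group
  ggplot2::ggplot(g, ggplot2::aes(x = stats::reorder(.data$name,
                                                     .data$model_id),
                                  y = .data$mean_weight)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_weight - .data$sem_weight,
      ymax = .data$mean_weight + .data$sem_weight
    ), width = 0.3) +
    ggplot2::labs(x = NULL, y = "mean Bayesian weight") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
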
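# ggplot2 views of experiment results.

#' Plot classification performance across training percentages
#'
#' One line per feature version, facetted by metric (accuracy, AUROC),
#' for a chosen ground truth-rarity dataset.
#'
#' @param object A `funalign_experiment`.
#' @param k,rarity Which ground-truth configuration to show (defaults: the
#'   first present).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.funalign_experiment <- function(object, k = NULL, rarity = NULL, ...) {
  df <- object$summary
  if (nrow(df) == 0L) abort("experiment has no summary metrics")
  k <- k %||% df$k[[1L]]
  rarity <- rarity %||% df$rarity[[1L]]
  df <- dplyr::filter(df, .data$k == !!k, .data$rarity == !!rarity) |>
    tidyr::pivot_longer(c("accuracy", "auroc"), names_to = "metric",
                        values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$y, y = .data$value,
                                   colour = .data$version)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "training percentage (y)", y = NULL,
                  colour = "feature version",
                  title = sprintf("classification performance (k=%s, rarity=%s)",
                                  k, rarity)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot precision/recall of the prediction sets
#'
#' Mean precision and recall over balanced replicates, per feature version
#' (consensus included) and training percentage.
#'
#' @param experiment A `funalign_experiment`.
#' @return A ggplot object.
#' @export
plot_prediction_metrics <- function(experiment) {
  df <- experiment$predictions
  if (nrow(df) == 0L) abort("experiment has no predictions")
  df <- df |>
    group_by(.data$version, .data$k, .data$rarity, .data$y) |>
    summarise(precision = mean(.data$precision, na.rm = TRUE),
              recall = mean(.data$recall), .groups = "drop") |>
    tidyr::pivot_longer(c("precision", "recall"), names_to = "metric",
                        values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$y), y = .data$value,
                                   fill = .data$version)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "training percentage (y)", y = NULL,
                  fill = "feature version") +
    ggplot2::theme_minimal()
}

#' Plot a noise robustness sweep
#'
#' Mean precision/recall (with per-seed points) against the noise fraction.
#'
#' @param object A [noise_sweep()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.noise_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("precision", "recall"),
                              names_to = "metric", values_to = "value")
  means <- long |>
    group_by(.data$fraction, .data$metric) |>
    summarise(value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$fraction, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_line(data = means, linewidth = 1) +
    ggplot2::labs(x = "noise fraction", y = NULL, colour = NULL,
                  title = "functional prediction vs. data noise") +
    ggplot2::theme_minimal()
}
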
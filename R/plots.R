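#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the training PLL curves
#'
#' @param object A `trained_rbm`.
#' @param ... Unused.
#' @returns A ggplot: PLL per epoch for train and validation sets.
#' @export
autoplot.trained_rbm <- function(object, ...) {
  ggplot2::ggplot(pll_history(object),
                  ggplot2::aes(x = .data$epoch, y = .data$pll,
                               colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "pseudo-log-likelihood (nats/sample)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

# Shared residue-by-position heatmap; diverging scale for signed values,
# sequential for probabilities
tile_plot <- function(df, fill_lab, diverging = TRUE) {
  sc <- if (diverging) {
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  midpoint = 0)
  } else {
    ggplot2::scale_fill_gradient(low = "white", high = "darkred")
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                   y = factor(.data$residue,
                                              levels = rev(aa_alphabet)),
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    sc +
    ggplot2::labs(x = "position", y = NULL, fill = fill_lab) +
    ggplot2::theme_minimal()
}

#' Heatmaps of aRBM parameters
#'
#' One residue-by-position panel per hidden-unit group plus the visible
#' bias, mirroring the standard way consensus weights are inspected.
#'
#' @param object An `average_rbm`.
#' @param ... Unused.
#' @returns A ggplot with one facet per group and one for the visible bias.
#' @export
autoplot.average_rbm <- function(object, ...) {
  td <- tidy(object)
  df <- dplyr::bind_rows(
    td |> dplyr::filter(.data$term == "weight") |>
      dplyr::mutate(panel = paste("group", .data$unit)),
    td |> dplyr::filter(.data$term == "visible_bias") |>
      dplyr::mutate(panel = "visible bias"))
  tile_plot(df, "value") + ggplot2::facet_wrap(~panel)
}

#' Per-state probability panels
#'
#' The hidden-state residue tables of a decomposition, ranked by
#' frequency, as heatmap facets (columns are probabilities summing to 1).
#'
#' @param object A `state_decomposition`.
#' @param ... Unused.
#' @returns A ggplot faceted by state label.
#' @export
autoplot.state_decomposition <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::mutate(panel = sprintf("%s %s f=%.3f", .data$label,
                                  .data$state_label, .data$frequency),
                  value = .data$prob)
  tile_plot(df, "probability", diverging = FALSE) +
    ggplot2::facet_wrap(~panel)
}

#' Scatter of the weight PCA
#'
#' One point per amino acid in the (PC1, PC2) plane.
#'
#' @param object A `group_pca`.
#' @param ... Unused.
#' @returns A ggplot.
#' @export
autoplot.group_pca <- function(object, ...) {
  ggplot2::ggplot(object$coords, ggplot2::aes(x = .data$pc1, y = .data$pc2,
                                              label = .data$residue)) +
    ggplot2::geom_text() +
    ggplot2::labs(
      x = sprintf("PC1 (%.0f%%)", 100 * object$explained[1]),
      y = sprintf("PC2 (%.0f%%)", 100 * object$explained[2])) +
    ggplot2::theme_minimal()
}

#' Plot a model-complexity scan
#'
#' Group count vs `N_h` (with the identity line: the regime where every
#' hidden unit is reproducibly recovered), noise fraction, and the mean
#' validation PLL.
#'
#' @param object A `complexity_scan`.
#' @param ... Unused.
#' @returns A ggplot with one facet per monitored quantity.
#' @export
autoplot.complexity_scan <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            c("n_groups", "noise_fraction", "pll_valid"),
                            names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_hidden, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "number of hidden units", y = NULL) +
    ggplot2::theme_minimal()
}
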
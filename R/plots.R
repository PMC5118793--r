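#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a space-time diagram
#'
#' Raster view of the diagram: columns are nodes (optionally ordered by
#' degree), rows are time steps running downward, white = alive, black =
#' dead.
#'
#' @param object An `llna_diagram`.
#' @param net Optional tessellation; when given, columns are ordered by
#'   ascending degree (visualization convention).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.llna_diagram <- function(object, net = NULL, ...) {
  if (!is.null(net)) object <- order_by_degree(object, net)
  df <- tidyr::expand_grid(time = seq_len(nrow(object)) - 1L,
                           node = seq_len(ncol(object)))
  df$state <- as.vector(t(unclass(object)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$node, y = .data$time,
                                   fill = factor(.data$state))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`0` = "black", `1` = "white"),
                               name = "state",
                               labels = c(`0` = "dead", `1` = "alive")) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(title = attr(object, "rule"), x = "node", y = "time") +
    ggplot2::theme_minimal()
}

#' Plot the three measurement distributions
#'
#' Histograms of per-node entropy, pooled word lengths and per-node
#' Lempel-Ziv complexity for one measured diagram.
#'
#' @param object An `llna_measures`.
#' @param bins Bins for the entropy/LZ panels.
#' @param ... Ignored.
#' @return A ggplot object (faceted).
#' @export
autoplot.llna_measures <- function(object, bins = 20, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(measure = "Shannon entropy", value = object$nodes$entropy),
    tibble::tibble(measure = "word length",
                   value = as.numeric(object$word_lengths)),
    tibble::tibble(measure = "Lempel-Ziv", value = object$nodes$lz)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                            colour = "grey20") +
    ggplot2::facet_wrap(~measure, scales = "free") +
    ggplot2::labs(x = NULL, y = "count") +
    ggplot2::theme_minimal()
}

#' Plot per-repetition CV accuracies
#'
#' @param object An `llna_cv`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.llna_cv <- function(object, ...) {
  df <- tibble::tibble(repetition = seq_along(object$accuracies),
                       accuracy = object$accuracies)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$repetition,
                                   y = .data$accuracy)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$mean_accuracy,
                        linetype = "dashed") +
    ggplot2::labs(y = "accuracy (%)") +
    ggplot2::theme_minimal()
}
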
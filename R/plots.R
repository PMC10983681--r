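#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_tile geom_text
#'   facet_wrap labs scale_fill_gradient theme_minimal
#' @export
ggplot2::autoplot

#' Plot hierarchical series, one panel per node
#'
#' @param series Data frame `period, node, value`.
#' @param nodes Optional subset of node labels (panel order).
#' @return A ggplot object.
#' @examples
#' plot_series(simulate_donations(seed = 1), nodes = c("Total", "M", "F"))
#' @export
plot_series <- function(series, nodes = NULL) {
  if (!is.null(nodes)) {
    series <- filter(series, .data$node %in% nodes)
  } else {
    nodes <- unique(series$node)
  }
  series %>%
    mutate(node = factor(.data$node, levels = nodes)) %>%
    ggplot(aes(x = .data$period, y = .data$value)) +
    geom_line(colour = "#00468B") +
    facet_wrap(~node, scales = "free_y") +
    labs(x = NULL, y = "blood units") +
    theme_minimal()
}

#' Plot history and coherent forecasts together
#'
#' Historical series as solid lines, reconciled forecasts as dashed lines,
#' one panel per node.
#'
#' @param history Data frame `period, node, value`.
#' @param forecasts Forecast tibble with `period`, `node`, `value` (e.g.
#'   from [run_pipeline()]).
#' @param nodes Optional subset of node labels.
#' @return A ggplot object.
#' @export
plot_forecast <- function(history, forecasts, nodes = NULL) {
  h <- mutate(history, part = "history")
  f <- mutate(as_tibble(forecasts), part = "forecast")
  df <- bind_rows(h[c("period", "node", "value", "part")],
                  f[c("period", "node", "value", "part")])
  if (!is.null(nodes)) {
    df <- filter(df, .data$node %in% nodes)
  } else {
    nodes <- unique(history$node)
  }
  df %>%
    mutate(node = factor(.data$node, levels = nodes)) %>%
    ggplot(aes(x = .data$period, y = .data$value,
               linetype = .data$part)) +
    geom_line(colour = "#00468B") +
    facet_wrap(~node, scales = "free_y") +
    labs(x = NULL, y = "blood units", linetype = NULL) +
    theme_minimal()
}

#' Heatmap of an accuracy table
#'
#' @param object An [accuracy_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot accuracy_table
#' @export
autoplot.accuracy_table <- function(object, ...) {
  long <- tidy.accuracy_table(object)
  long %>%
    mutate(column = factor(paste(.data$model, .data$method, sep = "_"),
                           levels = attr(object, "column_order")),
           node = factor(.data$node, levels = rev(object$node))) %>%
    ggplot(aes(x = .data$column, y = .data$node, fill = .data$mape)) +
    geom_tile() +
    geom_text(aes(label = sprintf("%.2f", .data$mape)), size = 3) +
    scale_fill_gradient(low = "#E8F4FA", high = "#ED0000") +
    labs(x = NULL, y = NULL, fill = "MAPE (%)") +
    theme_minimal()
}
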
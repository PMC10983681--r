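#' Read and write hierarchy configuration files
#'
#' The on-disk hierarchy format is a small YAML (or JSON) document with a
#' single `children` mapping from each internal node to the list of its
#' children. An example reproducing the blood donation tree ships with the
#' package: `system.file("extdata", "blood_hierarchy.yml",
#' package = "donorcast")`.
#'
#' @param path File path.
#' @return `read_hierarchy()` returns a [hierarchy_spec()];
#'   `write_hierarchy()` returns `path` invisibly.
#' @examples
#' read_hierarchy(system.file("extdata", "blood_hierarchy.yml",
#'                            package = "donorcast"))
#' @export
read_hierarchy <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$children)) {
    abort("Hierarchy file must contain a `children` mapping.",
          class = "donorcast_error_config")
  }
  hierarchy_spec(lapply(doc$children, as.character))
}

#' @rdname read_hierarchy
#' @param spec A [hierarchy_spec()].
#' @export
write_hierarchy <- function(spec, path) {
  stopifnot(inherits(spec, "hierarchy_spec"))
  kids <- split(names(spec$parent_of), spec$parent_of)
  # preserve canonical child order
  kids <- lapply(kids, function(k) k[order(match(k, spec$nodes))])
  kids <- kids[order(match(names(kids), spec$nodes))]
  yaml::write_yaml(list(children = kids), path)
  invisible(path)
}

#' Read and write long-format series files
#'
#' Series travel as CSV with columns `period` (ISO year-month, `YYYY-MM`),
#' `node` and `value`. Reading validates the panel: every node must be
#' observed at every period, months must be contiguous, and (when a `spec`
#' is supplied) node labels must belong to the hierarchy. Writing uses a
#' full-precision shortest round-trip representation, so
#' `read_series_csv(write_series_csv(x))` reproduces `x` exactly.
#'
#' @param path File path.
#' @param spec Optional [hierarchy_spec()] used to check node labels.
#' @return `read_series_csv()` returns a tibble `period, node, value`
#'   (with `period` a month-start `Date`); writers return `path`
#'   invisibly.
#' @export
read_series_csv <- function(path, spec = NULL) {
  df <- readr::read_csv(path, col_types = readr::cols(
    period = readr::col_character(),
    node = readr::col_character(),
    value = readr::col_double()))
  if (!all(c("period", "node", "value") %in% names(df))) {
    abort("Series CSV must have columns period, node, value.",
          class = "donorcast_error_config")
  }
  period <- as.Date(paste0(df$period, "-01"))
  if (anyNA(period)) {
    abort(paste0("Unparseable period(s): ",
                 paste(unique(df$period[is.na(period)]), collapse = ", "),
                 " (expected YYYY-MM)."),
          class = "donorcast_error_config")
  }
  df$period <- period
  if (!is.null(spec)) {
    unknown <- setdiff(unique(df$node), spec$nodes)
    if (length(unknown)) {
      abort(paste0("Unknown node label(s): ",
                   paste(unknown, collapse = ", ")),
            class = "donorcast_error_label")
    }
  }
  periods <- sort(unique(df$period))
  expected <- seq(min(periods), max(periods), by = "month")
  gaps <- setdiff(format(expected, "%Y-%m"), format(periods, "%Y-%m"))
  if (length(gaps)) {
    abort(paste0("Missing month(s): ", paste(gaps, collapse = ", ")),
          class = "donorcast_error_gap")
  }
  nodes <- unique(df$node)
  full <- tidyr::expand_grid(period = periods, node = nodes)
  miss <- dplyr::anti_join(full, df, by = c("period", "node"))
  if (nrow(miss)) {
    abort(paste0("Missing period x node cell(s), e.g. ",
                 format(miss$period[1], "%Y-%m"), " / ", miss$node[1],
                 " (", nrow(miss), " total)."),
          class = "donorcast_error_gap")
  }
  if (nrow(df) != nrow(full)) {
    abort("Duplicated period x node rows.",
          class = "donorcast_error_config")
  }
  node_order <- if (!is.null(spec)) spec$nodes else nodes
  df %>%
    arrange(.data$period, factor(.data$node, levels = node_order)) %>%
    as_tibble()
}

#' @rdname read_series_csv
#' @param series Data frame `period, node, value`.
#' @export
write_series_csv <- function(series, path) {
  out <- series %>%
    mutate(period = format(.data$period, "%Y-%m")) %>%
    select("period", "node", "value")
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname read_series_csv
#' @param forecasts A reconciled forecast tibble with columns `step`,
#'   `node`, `value`, `method` and optionally `period` and `base_model`.
#' @param round_units Round values to whole donation units on export?
#' @export
write_forecast_csv <- function(forecasts, path, round_units = FALSE) {
  out <- as_tibble(forecasts)
  if (!"period" %in% names(out)) out$period <- NA_character_
  if (!"base_model" %in% names(out)) out$base_model <- NA_character_
  if (inherits(out$period, "Date")) {
    out$period <- format(out$period, "%Y-%m")
  }
  if (round_units) out$value <- round(out$value)
  readr::write_csv(out[c("step", "period", "node", "value", "method",
                         "base_model")], path)
  invisible(path)
}

#' Published validation totals: monthly actual vs forecast
#'
#' The published two-year holdout for the national totals: twelve months of
#' actual and forecast donations for 2019 (pre-pandemic) and twelve for
#' 2020 (Covid-disrupted). Recomputing the yearly MAPEs from these pairs
#' gives 14.80 (2019) and 84.06 (2020).
#'
#' @return A tibble `period, node, actual, forecast` (24 rows,
#'   node `"Total"`).
#' @examples
#' t5 <- nbsz_validation_totals()
#' mape(t5$actual[1:12], t5$forecast[1:12])
#' @export
nbsz_validation_totals <- function() {
  path <- system.file("extdata", "nbsz_validation_totals.csv",
                      package = "donorcast")
  df <- readr::read_csv(path, col_types = "ccdd")
  df$period <- as.Date(paste0(df$period, "-01"))
  as_tibble(df)
}

#' Published accuracy averages: the reported Average MAPE row
#'
#' The published method-comparison averages: the `Average` row of the
#' MAPE table over (ets, arima) x (bu, tdfp, tdha, tdhp, oc). The
#' underlying registry data are not public, so only this summary row is
#' packaged; it exercises the selection rule (the minimum, 11.30, sits at
#' tdfp under arima).
#'
#' @return A one-row tibble shaped like an [accuracy_table()] (a `node`
#'   column equal to `"Average"` plus ten `<model>_<method>` columns).
#' @examples
#' select_best(nbsz_accuracy_averages())
#' @export
nbsz_accuracy_averages <- function() {
  path <- system.file("extdata", "nbsz_accuracy_averages.csv",
                      package = "donorcast")
  long <- readr::read_csv(path, col_types = "ccd")
  wide <- long %>%
    mutate(column = paste(.data$model, .data$method, sep = "_")) %>%
    select("column", "mape") %>%
    tidyr::pivot_wider(names_from = "column", values_from = "mape")
  bind_cols(tibble(node = "Average"), wide)
}
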
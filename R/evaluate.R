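#' Mean absolute percentage error
#'
#' `100 * mean(|y - yhat| / y)` over aligned actual/forecast pairs, the
#' accuracy measure used for method comparison and holdout validation.
#' Zero actuals are an error — percentage errors are undefined there and
#' silently skipping periods would bias the comparison.
#'
#' @param actual,predicted Equal-length numeric vectors; `actual` must be
#'   nonzero everywhere.
#' @return A single percentage (e.g. `14.8` for 14.8%).
#' @examples
#' mape(c(100, 200), c(90, 220))  # 10%
#' @export
mape <- function(actual, predicted) {
  if (length(actual) != length(predicted) || length(actual) < 1) {
    abort("`actual` and `predicted` must have equal length >= 1.",
          class = "donorcast_error_argument")
  }
  if (anyNA(actual) || anyNA(predicted)) {
    abort("Missing values in actual/predicted.",
          class = "donorcast_error_argument")
  }
  if (any(actual == 0)) {
    abort("Zero actual value(s): percentage error undefined.",
          class = "donorcast_error_zero_actual")
  }
  100 * mean(abs(actual - predicted) / abs(actual))
}

#' Out-of-sample accuracy table over methods and base models
#'
#' Fits each base model on `history`, reconciles its forecasts with each
#' method, forecasts the holdout span, and computes the MAPE per node; an
#' `Average` row (arithmetic mean over the node rows) is appended. The
#' layout mirrors the standard method-comparison table: one row per node
#' plus `Average`, one column per (base model, method) pair.
#'
#' @param history,holdout Data frames `period, node, value` over the same
#'   hierarchy; `holdout` must start the month after `history` ends.
#' @param spec A [hierarchy_spec()].
#' @param methods Reconciliation methods to evaluate (column order).
#' @param base_models Base models to evaluate: subset of
#'   `c("ets", "arima")` (block order).
#' @param within,oc_weights Passed to [reconcile()].
#' @param ... Passed to the base-model fitting functions.
#' @return An `accuracy_table`: a tibble with a `node` column and one
#'   numeric MAPE column per `<model>_<method>` pair; attribute
#'   `"column_order"` records the canonical ordering. Supports
#'   [generics::tidy()] and [autoplot][autoplot.accuracy_table].
#' @examples
#' \donttest{
#' x <- simulate_donations(seed = 1)
#' spl <- split_history(x, holdout = 12)
#' accuracy_table(spl$history, spl$holdout, blood_hierarchy(),
#'                base_models = "ets")
#' }
#' @export
accuracy_table <- function(history, holdout, spec,
                           methods = c("bu", "tdfp", "tdha", "tdhp", "oc"),
                           base_models = c("ets", "arima"),
                           within = c("total", "parent"),
                           oc_weights = NULL, ...) {
  stopifnot(inherits(spec, "hierarchy_spec"))
  base_models <- match.arg(base_models, several.ok = TRUE)
  methods <- match.arg(methods, several.ok = TRUE)
  hm <- .series_matrix(history, nodes = spec$nodes)
  om <- .series_matrix(holdout, nodes = spec$nodes)
  hp <- attr(hm, "periods")
  op <- attr(om, "periods")
  if (inherits(hp, "Date") && inherits(op, "Date")) {
    if (min(op) <= max(hp)) {
      abort("Holdout must come strictly after the history window.",
            class = "donorcast_error_chronology")
    }
    if (!identical(format(min(op), "%Y-%m"),
                   format(.next_month(max(hp)), "%Y-%m"))) {
      abort("Holdout must start the month after the history ends.",
            class = "donorcast_error_chronology")
    }
  }
  h <- nrow(om)

  cols <- list()
  for (mod in base_models) {
    base <- base_forecasts(history, spec, h = h, model = mod, ...)
    for (met in methods) {
      rec <- reconcile(base, spec, method = met, history = history,
                       oc_weights = oc_weights, within = within)
      rm_ <- .bf_matrix(rec, spec$nodes, what = "reconciled forecast")
      cols[[paste(mod, met, sep = "_")]] <-
        unname(vapply(spec$nodes, function(nd) mape(om[, nd], rm_[, nd]),
                      numeric(1)))
    }
  }
  tab <- bind_cols(tibble(node = spec$nodes), as_tibble(cols))
  avg <- tab %>% summarise(across(-"node", mean)) %>%
    mutate(node = "Average", .before = 1)
  out <- bind_rows(tab, avg)
  attr(out, "column_order") <- names(cols)
  class(out) <- c("accuracy_table", class(out))
  out
}

.next_month <- function(d) {
  seq(d, by = "month", length.out = 2)[2]
}

#' Split a series into history and holdout windows
#'
#' @param series Data frame `period, node, value`.
#' @param holdout Number of final periods reserved for validation.
#' @return A list with tibbles `history` and `holdout`.
#' @examples
#' spl <- split_history(simulate_donations(seed = 1), holdout = 12)
#' range(spl$history$period); range(spl$holdout$period)
#' @export
split_history <- function(series, holdout = 12L) {
  periods <- sort(unique(series$period))
  if (holdout < 1 || holdout >= length(periods)) {
    abort("`holdout` must be in [1, number of periods - 1].",
          class = "donorcast_error_argument")
  }
  cut <- periods[length(periods) - holdout]
  list(history = dplyr::filter(series, .data$period <= cut),
       holdout = dplyr::filter(series, .data$period > cut))
}

#' Select the best (method, base model) column of an accuracy table
#'
#' Returns the column with the smallest `Average` MAPE. Ties are broken
#' deterministically by the canonical column order — methods
#' (bu, tdfp, tdha, tdhp, oc) crossed with models (ets, arima), method
#' varying slowest — and a tie triggers a message.
#'
#' @param table An [accuracy_table()], or any data frame with a `node`
#'   column containing an `"Average"` row and `<model>_<method>` MAPE
#'   columns.
#' @return A one-row tibble `method, model, mape` (the unrounded Average
#'   MAPE of the winning column).
#' @examples
#' printed <- tibble::tibble(node = "Average",
#'   ets_bu = 12.58, ets_tdfp = 12.65, ets_tdha = 12.62, ets_tdhp = 12.43,
#'   ets_oc = 12.57, arima_bu = 12.0, arima_tdfp = 11.3,
#'   arima_tdha = 11.52, arima_tdhp = 11.52, arima_oc = 11.52)
#' select_best(printed)  # tdfp under arima, 11.3
#' @export
select_best <- function(table) {
  stopifnot(is.data.frame(table), "node" %in% names(table))
  avg <- table[table$node == "Average", , drop = FALSE]
  if (nrow(avg) != 1L) {
    abort("Accuracy table must contain exactly one 'Average' row.",
          class = "donorcast_error_argument")
  }
  cols <- setdiff(names(table), "node")
  if (!length(cols)) {
    abort("Accuracy table has no method columns.",
          class = "donorcast_error_argument")
  }
  parts <- strsplit(cols, "_", fixed = TRUE)
  meta <- tibble(
    column = cols,
    model = vapply(parts, `[[`, character(1), 1),
    method = vapply(parts, function(p) paste(p[-1], collapse = "_"),
                    character(1)),
    mape = as.numeric(unlist(avg[1, cols])))
  tie_order <- order(match(meta$method, c("bu", "tdfp", "tdha", "tdhp",
                                          "oc")),
                     match(meta$model, c("ets", "arima")))
  meta <- meta[tie_order, ]
  best <- meta[which.min(meta$mape), ]
  if (sum(abs(meta$mape - best$mape) < .Machine$double.eps^0.5) > 1L) {
    message("Tie on Average MAPE; keeping the first column in canonical ",
            "order (", best$model, "_", best$method, ").")
  }
  tibble(method = best$method, model = best$model, mape = best$mape)
}

#' Validate forecasts against actuals for one node
#'
#' Aligns a reconciled forecast set with observed values at one node and
#' reports the absolute percentage error per period plus the MAPE over each
#' calendar-year window (and overall).
#'
#' @param forecasts Data frame with columns `node`, `value` and either
#'   `period` or `step`; steps are mapped onto the actual periods in order.
#' @param actual Data frame `period, node, value` of observed values.
#' @param node Node label to validate (default the first in `forecasts`).
#' @return A `validation_report` tibble `period, actual, forecast, ape`
#'   (APE in percent) with attributes `mape_by_year` (tibble `year, mape`)
#'   and `mape` (overall); see [mape_by_year()].
#' @examples
#' t5 <- nbsz_validation_totals()
#' rep <- validate_holdout(dplyr::select(t5, period, node,
#'                                       value = forecast),
#'                         dplyr::select(t5, period, node,
#'                                       value = actual))
#' mape_by_year(rep)
#' @export
validate_holdout <- function(forecasts, actual, node = NULL) {
  stopifnot(is.data.frame(forecasts), is.data.frame(actual))
  node <- node %||% forecasts$node[[1]]
  f <- dplyr::filter(forecasts, .data$node == !!node)
  a <- dplyr::filter(actual, .data$node == !!node)
  if (!nrow(f) || !nrow(a)) {
    abort(paste0("No rows for node '", node, "'."),
          class = "donorcast_error_label")
  }
  a <- arrange(a, .data$period)
  if ("period" %in% names(f)) {
    f <- arrange(f, .data$period)
    joined <- dplyr::inner_join(
      select(a, "period", actual = "value"),
      select(f, "period", forecast = "value"), by = "period")
    if (nrow(joined) != nrow(a)) {
      abort("Forecast and actual periods do not align.",
            class = "donorcast_error_chronology")
    }
  } else {
    f <- arrange(f, .data$step)
    if (nrow(f) < nrow(a)) {
      abort("Fewer forecast steps than actual periods.",
            class = "donorcast_error_chronology")
    }
    joined <- tibble(period = a$period, actual = a$value,
                     forecast = f$value[seq_len(nrow(a))])
  }
  if (any(joined$actual == 0)) {
    abort("Zero actual value(s): percentage error undefined.",
          class = "donorcast_error_zero_actual")
  }
  joined$ape <- 100 * abs(joined$actual - joined$forecast) / joined$actual
  yearly <- joined %>%
    mutate(year = as.integer(format(.data$period, "%Y"))) %>%
    group_by(.data$year) %>%
    summarise(mape = mean(.data$ape), .groups = "drop")
  attr(joined, "mape_by_year") <- yearly
  attr(joined, "mape") <- mean(joined$ape)
  attr(joined, "node") <- node
  class(joined) <- c("validation_report", class(joined))
  joined
}

#' @rdname validate_holdout
#' @param report A `validation_report`.
#' @export
mape_by_year <- function(report) {
  stopifnot(inherits(report, "validation_report"))
  attr(report, "mape_by_year")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> node", attr(x, "node"), "- overall MAPE",
      sprintf("%.2f\n", attr(x, "mape")))
  print(attr(x, "mape_by_year"))
  NextMethod()
}

#' @rdname accuracy_table
#' @param x An `accuracy_table`.
#' @method tidy accuracy_table
#' @export
tidy.accuracy_table <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), -"node", names_to = c("model", "method"),
                      names_sep = "_", values_to = "mape")
}
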
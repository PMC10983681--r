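#' Configure an end-to-end forecasting run
#'
#' Bundles everything [run_pipeline()] needs: the data, the hierarchy, the
#' candidate base models and reconciliation methods, the evaluation split
#' and the forecast horizon.
#'
#' @param series A long series data frame (`period, node, value`) or the
#'   path to a series CSV.
#' @param hierarchy A [hierarchy_spec()] or the path to a hierarchy YAML;
#'   default the blood donation tree.
#' @param base_models Candidate base models (`"ets"`, `"arima"`).
#' @param methods Candidate reconciliation methods.
#' @param horizon Months to forecast after model selection (default 60,
#'   five years).
#' @param holdout Months reserved for out-of-sample evaluation
#'   (default 12).
#' @param seed Integer seed fixed at the start of the run.
#' @param out_dir Directory for output files; `NULL` keeps everything
#'   in memory.
#' @param round_output Round exported forecasts to whole units?
#' @return A `run_config` list, validated.
#' @export
run_config <- function(series, hierarchy = blood_hierarchy(),
                       base_models = c("ets", "arima"),
                       methods = c("bu", "tdfp", "tdha", "tdhp", "oc"),
                       horizon = 60L, holdout = 12L, seed = 1L,
                       out_dir = NULL, round_output = FALSE) {
  if (is.character(hierarchy)) hierarchy <- read_hierarchy(hierarchy)
  stopifnot(inherits(hierarchy, "hierarchy_spec"))
  if (is.character(series)) series <- read_series_csv(series, hierarchy)
  base_models <- match.arg(base_models, c("ets", "arima"),
                           several.ok = TRUE)
  methods <- match.arg(methods, c("bu", "tdfp", "tdha", "tdhp", "oc"),
                       several.ok = TRUE)
  n_periods <- length(unique(series$period))
  if (horizon < 1) {
    abort("`horizon` must be >= 1.", class = "donorcast_error_config")
  }
  if (holdout < 1 || holdout >= n_periods) {
    abort("`holdout` must be in [1, number of periods - 1].",
          class = "donorcast_error_config")
  }
  structure(list(series = as_tibble(series), hierarchy = hierarchy,
                 base_models = base_models, methods = methods,
                 horizon = as.integer(horizon),
                 holdout = as.integer(holdout), seed = as.integer(seed),
                 out_dir = out_dir, round_output = isTRUE(round_output)),
            class = "run_config")
}

#' Run the full forecasting workflow
#'
#' Executes the complete analysis: split off a holdout window, fit every
#' base model, reconcile with every method, score each combination by
#' out-of-sample MAPE, select the winner, refit it on the full history and
#' forecast `horizon` months ahead. When `out_dir` is set the accuracy
#' table (CSV + JSON), the coherent forecast table, the selection and a run
#' log (including the configuration hash, so identical configurations are
#' recognisable) are written to disk.
#'
#' @param config A [run_config()].
#' @return A `donorcast_run` list: `accuracy`
#'   (the [accuracy_table()]), `best` (from [select_best()]), `forecasts`
#'   (tibble `step, period, node, value, method, base_model`, coherent),
#'   `log` (character lines) and `paths` (written files, if any).
#' @examples
#' \donttest{
#' cfg <- run_config(simulate_donations(seed = 1), horizon = 12,
#'                   base_models = "ets")
#' run <- run_pipeline(cfg)
#' run$best
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  spec <- config$hierarchy
  series <- config$series
  log <- c(paste0("donorcast run, config hash ", rlang::hash(
    config[setdiff(names(config), "out_dir")])),
    paste0("series: ", length(unique(series$period)), " months x ",
           length(unique(series$node)), " nodes"))

  spl <- split_history(series, holdout = config$holdout)
  acc <- accuracy_table(spl$history, spl$holdout, spec,
                        methods = config$methods,
                        base_models = config$base_models)
  avg <- acc[acc$node == "Average", , drop = FALSE]
  for (col in setdiff(names(avg), "node")) {
    log <- c(log, sprintf("average MAPE %-12s %.4f", col, avg[[col]]))
  }
  best <- select_best(acc)
  log <- c(log, sprintf("selected: %s under %s (average MAPE %.4f)",
                        best$method, best$model, best$mape))

  base <- base_forecasts(series, spec, h = config$horizon,
                         model = best$model)
  recon <- reconcile(base, spec, method = best$method, history = series)
  last <- max(series$period)
  future <- seq(.next_month(last), by = "month",
                length.out = config$horizon)
  forecasts <- recon %>%
    mutate(period = future[.data$step], base_model = best$model) %>%
    select("step", "period", "node", "value", "method", "base_model")

  paths <- character()
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$out_dir, f)
    readr::write_csv(as_tibble(acc), p("accuracy_table.csv"))
    jsonlite::write_json(
      list(accuracy = as_tibble(acc), best = best),
      p("accuracy_table.json"), dataframe = "rows", digits = NA)
    write_forecast_csv(forecasts, p("forecast_table.csv"),
                       round_units = config$round_output)
    writeLines(log, p("run_log.txt"))
    paths <- c(accuracy_csv = p("accuracy_table.csv"),
               accuracy_json = p("accuracy_table.json"),
               forecast_csv = p("forecast_table.csv"),
               log = p("run_log.txt"))
  }
  structure(list(accuracy = acc, best = best, forecasts = forecasts,
                 log = log, paths = paths, config = config),
            class = "donorcast_run")
}

#' @export
print.donorcast_run <- function(x, ...) {
  cat("<donorcast_run>\n")
  cat(" best:", x$best$method, "under", x$best$model,
      sprintf("(average MAPE %.2f)\n", x$best$mape))
  cat(" forecast:", length(unique(x$forecasts$step)), "months x",
      length(unique(x$forecasts$node)), "nodes\n")
  if (length(x$paths)) cat(" outputs:", paste(x$paths, collapse = ", "),
                           "\n")
  invisible(x)
}
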
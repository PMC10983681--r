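#' Independent base forecasts for every node of a hierarchy
#'
#' Fits a univariate model ([fit_auto_arima()] or [fit_hw()]) to each node's
#' series independently and produces `h` point forecasts per node. The
#' results are incoherent in general — parents need not equal the sum of
#' their children — and are the input every reconciliation method operates
#' on.
#'
#' @param series Data frame `period, node, value` covering every node.
#' @param spec A [hierarchy_spec()].
#' @param h Forecast horizon (steps ahead).
#' @param model `"arima"` or `"ets"`.
#' @param ... Passed on to the fitting function.
#' @return A tibble `node, step, value, model` with one forecast per node
#'   and step, nodes in canonical order.
#' @examples
#' x <- simulate_donations(seed = 1)
#' base_forecasts(x, blood_hierarchy(), h = 6, model = "ets")
#' @export
base_forecasts <- function(series, spec, h, model = c("arima", "ets"), ...) {
  model <- match.arg(model)
  stopifnot(inherits(spec, "hierarchy_spec"))
  m <- .series_matrix(series, nodes = spec$nodes)
  purrr::map_dfr(spec$nodes, function(nd) {
    fit <- switch(model,
                  arima = fit_auto_arima(m[, nd], ...),
                  ets = fit_hw(m[, nd], ...))
    tibble(node = nd, step = seq_len(h), value = forecast(fit, h),
           model = model)
  })
}

# base-forecast tibble -> steps x nodes matrix for the requested nodes
.bf_matrix <- function(base, nodes, what = "base forecast") {
  stopifnot(all(c("node", "step", "value") %in% names(base)))
  missing <- setdiff(nodes, unique(base$node))
  if (length(missing)) {
    abort(paste0("Missing ", what, " for node(s): ",
                 paste(missing, collapse = ", ")),
          class = "donorcast_error_incomplete")
  }
  wide <- base %>%
    filter(.data$node %in% nodes) %>%
    select("step", "node", "value") %>%
    tidyr::pivot_wider(names_from = "node", values_from = "value") %>%
    arrange(.data$step)
  m <- as.matrix(wide[nodes])
  if (anyNA(m)) {
    abort(paste0("Incomplete ", what, ": some node/step cells missing."),
          class = "donorcast_error_incomplete")
  }
  attr(m, "steps") <- wide$step
  m
}

.recon_tibble <- function(full, steps, nodes, method) {
  tibble(step = rep(steps, times = length(nodes)),
         node = rep(nodes, each = length(steps)),
         value = as.vector(full),
         method = method) %>%
    arrange(.data$step, factor(.data$node, levels = nodes)) %>%
    select("node", "step", "value", "method")
}

#' Bottom-up forecast reconciliation
#'
#' Keeps the bottom-level base forecasts unchanged and rebuilds every upper
#' node as the exact sum of its descendants via the summing matrix. Base
#' forecasts at upper nodes, if present, are ignored.
#'
#' @param base Base-forecast tibble (`node, step, value`), covering at least
#'   all bottom nodes at every step — see [base_forecasts()].
#' @param spec A [hierarchy_spec()].
#' @return A coherent tibble `node, step, value, method` with
#'   `method = "bu"`.
#' @examples
#' spec <- blood_hierarchy()
#' base <- tibble::tibble(node = spec$bottom, step = 1,
#'                        value = c(913, 698, 148, 1906, 721, 544, 116, 1496))
#' reconcile_bottom_up(base, spec)
#' @export
reconcile_bottom_up <- function(base, spec) {
  stopifnot(inherits(spec, "hierarchy_spec"))
  bm <- .bf_matrix(base, spec$bottom)
  S <- summing_matrix(spec)
  .recon_tibble(bm %*% t(S), attr(bm, "steps"), spec$nodes, "bu")
}

#' Top-down disaggregation proportions
#'
#' Three ways to split a top-level forecast across the bottom nodes:
#'
#' * `proportions_ahp()` — *average historical proportions*: each bottom
#'   node's proportion is the time average of its share,
#'   `p_i = mean_t(Y_i,t / Y_t)`. By default the share is taken against the
#'   root total at each period (the printed formula); `within = "parent"`
#'   instead multiplies mean within-parent shares down the ancestor chain.
#' * `proportions_pha()` — *proportions of historical averages*:
#'   `p_i = mean_t(Y_i,t) / mean_t(Y_t)`.
#' * `proportions_fp()` — *forecast proportions*: computed at every horizon
#'   step from the base forecasts themselves; each bottom node's proportion
#'   is the product, along its ancestor chain, of the node's base forecast
#'   divided by the summed base forecasts of that node and its siblings.
#'
#' Proportions are non-negative for non-negative inputs and sum to 1 across
#' bottom nodes (forecast proportions: at every step).
#'
#' @param history Data frame `period, node, value` with the historical
#'   series of every node.
#' @param spec A [hierarchy_spec()].
#' @param within `"total"` (default, share against the root total) or
#'   `"parent"` (two-stage within-parent shares) — `proportions_ahp()` only.
#' @return A `proportion_set`: a tibble `node, proportion` (plus `step` for
#'   forecast proportions) with attribute `method` one of `"tdhp"`,
#'   `"tdha"`, `"tdfp"`.
#' @examples
#' x <- simulate_donations(seed = 1)
#' proportions_ahp(x, blood_hierarchy())
#' @export
proportions_ahp <- function(history, spec, within = c("total", "parent")) {
  within <- match.arg(within)
  stopifnot(inherits(spec, "hierarchy_spec"))
  m <- .series_matrix(history, nodes = spec$nodes)
  if (within == "total") {
    tot <- m[, spec$root]
    if (any(tot == 0)) {
      abort("Top-level series has zero values; proportions undefined.",
            class = "donorcast_error_zero_total")
    }
    p <- colMeans(m[, spec$bottom, drop = FALSE] / tot)
  } else {
    p <- vapply(spec$bottom, function(b) {
      prob <- 1
      node <- b
      while (node != spec$root) {
        par <- spec$parent_of[[node]]
        den <- m[, par]
        if (any(den == 0)) {
          abort("A parent series has zero values; proportions undefined.",
                class = "donorcast_error_zero_total")
        }
        prob <- prob * mean(m[, node] / den)
        node <- par
      }
      prob
    }, numeric(1))
  }
  .proportion_set(tibble(node = spec$bottom, proportion = unname(p)),
                  "tdhp")
}

#' @rdname proportions_ahp
#' @export
proportions_pha <- function(history, spec) {
  stopifnot(inherits(spec, "hierarchy_spec"))
  m <- .series_matrix(history, nodes = spec$nodes)
  tot_mean <- mean(m[, spec$root])
  if (tot_mean == 0) {
    abort("Top-level series averages zero; proportions undefined.",
          class = "donorcast_error_zero_total")
  }
  p <- colMeans(m[, spec$bottom, drop = FALSE]) / tot_mean
  .proportion_set(tibble(node = spec$bottom, proportion = unname(p)),
                  "tdha")
}

#' @rdname proportions_ahp
#' @param base Base-forecast tibble covering every node and step
#'   (`proportions_fp()` only).
#' @export
proportions_fp <- function(base, spec) {
  stopifnot(inherits(spec, "hierarchy_spec"))
  bm <- .bf_matrix(base, spec$nodes)
  steps <- attr(bm, "steps")
  kids_of <- split(names(spec$parent_of), spec$parent_of)
  out <- purrr::map_dfr(seq_along(steps), function(s) {
    v <- bm[s, ]
    p <- vapply(spec$bottom, function(b) {
      prob <- 1
      node <- b
      while (node != spec$root) {
        sibs <- kids_of[[spec$parent_of[[node]]]]
        den <- sum(v[sibs])
        if (den == 0) {
          abort(paste0("Zero sibling-sum at step ", steps[s], " under ",
                       spec$parent_of[[node]], "; proportions undefined."),
                class = "donorcast_error_zero_total")
        }
        prob <- prob * v[[node]] / den
        node <- spec$parent_of[[node]]
      }
      prob
    }, numeric(1))
    tibble(node = spec$bottom, step = steps[s], proportion = unname(p))
  })
  .proportion_set(out, "tdfp")
}

.proportion_set <- function(tbl, method) {
  sums <- if ("step" %in% names(tbl)) {
    tbl %>% group_by(.data$step) %>%
      summarise(s = sum(.data$proportion)) %>% pull("s")
  } else {
    sum(tbl$proportion)
  }
  if (any(abs(sums - 1) > 1e-9)) {
    warn("Disaggregation proportions do not sum to 1 (within 1e-9).")
  }
  attr(tbl, "method") <- method
  class(tbl) <- c("proportion_set", class(tbl))
  tbl
}

#' Top-down forecast reconciliation
#'
#' Splits a top-level forecast across the bottom nodes using a
#' [proportion set][proportions_ahp()] and rebuilds the upper levels by
#' aggregation; the result is coherent and re-aggregates to the top
#' forecast exactly.
#'
#' @param top_forecast Numeric vector: the top node's forecast for steps
#'   `1..h`.
#' @param proportions A `proportion_set` from [proportions_ahp()],
#'   [proportions_pha()] or [proportions_fp()]; forecast proportions must
#'   cover every step of `top_forecast`.
#' @param spec A [hierarchy_spec()].
#' @return A coherent tibble `node, step, value, method`.
#' @examples
#' spec <- blood_hierarchy()
#' x <- simulate_donations(seed = 1)
#' p <- proportions_pha(x, spec)
#' reconcile_top_down(rep(5000, 3), p, spec)
#' @export
reconcile_top_down <- function(top_forecast, proportions, spec) {
  stopifnot(inherits(spec, "hierarchy_spec"),
            inherits(proportions, "proportion_set"))
  h <- length(top_forecast)
  if (!setequal(proportions$node, spec$bottom)) {
    abort("Proportions do not match the hierarchy's bottom nodes.",
          class = "donorcast_error_label")
  }
  if ("step" %in% names(proportions)) {
    if (!all(seq_len(h) %in% proportions$step)) {
      abort("Forecast proportions must cover every horizon step.",
            class = "donorcast_error_incomplete")
    }
    pm <- proportions %>%
      rename(value = "proportion") %>%
      .bf_matrix(spec$bottom, what = "proportion")
    pm <- pm[seq_len(h), , drop = FALSE]
  } else {
    p <- proportions$proportion[match(spec$bottom, proportions$node)]
    pm <- matrix(p, nrow = h, ncol = length(p), byrow = TRUE,
                 dimnames = list(NULL, spec$bottom))
  }
  bottom <- pm * top_forecast
  S <- summing_matrix(spec)
  .recon_tibble(bottom %*% t(S), seq_len(h), spec$nodes,
                attr(proportions, "method"))
}

#' Optimal-combination forecast reconciliation
#'
#' Regresses the full vector of base forecasts (all nodes) on the summing
#' matrix at each horizon step: the fitted generalised least-squares
#' coefficients are the reconciled bottom-level forecasts, and the
#' reconciled vector is their aggregation. With identity weights (the
#' default, ordinary least squares) this is the orthogonal projection
#' `S (S'S)^-1 S'` of the base forecasts onto the coherent subspace, so
#' already-coherent base forecasts pass through unchanged and the operation
#' is idempotent.
#'
#' @param base Base-forecast tibble covering every node at every step.
#' @param spec A [hierarchy_spec()].
#' @param weights Optional positive weights, one per node in canonical
#'   order (diagonal generalised least squares); `NULL` for ordinary least
#'   squares.
#' @return A coherent tibble `node, step, value, method` with
#'   `method = "oc"`.
#' @examples
#' spec <- hierarchy_spec(list(Total = c("a", "b")))
#' base <- tibble::tibble(node = c("Total", "a", "b"), step = 1,
#'                        value = c(10, 4, 4))
#' reconcile_oc(base, spec)  # children 14/3, total 28/3
#' @export
reconcile_oc <- function(base, spec, weights = NULL) {
  stopifnot(inherits(spec, "hierarchy_spec"))
  bm <- .bf_matrix(base, spec$nodes)
  S <- summing_matrix(spec)
  if (is.null(weights)) {
    W <- diag(nrow(S))
  } else {
    stopifnot(length(weights) == nrow(S), all(weights > 0))
    W <- diag(weights)
  }
  xtx <- t(S) %*% W %*% S
  beta <- tryCatch(
    solve(xtx, t(S) %*% W %*% t(bm)),
    error = function(e) {
      abort(paste0("Singular normal equations in optimal combination: ",
                   conditionMessage(e)),
            class = "donorcast_error_numerical")
    })
  .recon_tibble(t(S %*% beta), attr(bm, "steps"), spec$nodes, "oc")
}

#' Reconcile base forecasts by any supported method
#'
#' One entry point over [reconcile_bottom_up()], [reconcile_top_down()]
#' (with each of the three proportion schemes) and [reconcile_oc()].
#' Top-down methods take the top node's forecast from `base` and, for the
#' historical-proportion schemes, compute proportions from `history`.
#'
#' @param base Base-forecast tibble from [base_forecasts()].
#' @param spec A [hierarchy_spec()].
#' @param method `"bu"`, `"tdfp"`, `"tdha"`, `"tdhp"` or `"oc"`.
#' @param history Historical series (`period, node, value`), required for
#'   `"tdha"` and `"tdhp"`.
#' @param oc_weights Optional diagonal weights for `"oc"`.
#' @param within Passed to [proportions_ahp()] for `"tdhp"`.
#' @return A coherent tibble `node, step, value, method`.
#' @examples
#' x <- simulate_donations(seed = 1)
#' spec <- blood_hierarchy()
#' base <- base_forecasts(x, spec, h = 6, model = "ets")
#' reconcile(base, spec, "tdha", history = x)
#' @export
reconcile <- function(base, spec,
                      method = c("bu", "tdfp", "tdha", "tdhp", "oc"),
                      history = NULL, oc_weights = NULL,
                      within = c("total", "parent")) {
  method <- match.arg(method)
  if (method %in% c("tdha", "tdhp") && is.null(history)) {
    abort(paste0("Method '", method, "' needs `history` to compute ",
                 "historical proportions."),
          class = "donorcast_error_argument")
  }
  if (method %in% c("tdfp", "tdha", "tdhp")) {
    top <- base %>% filter(.data$node == spec$root) %>%
      arrange(.data$step) %>% pull("value")
    if (!length(top)) {
      abort("Top-down methods need a base forecast for the root node.",
            class = "donorcast_error_incomplete")
    }
  }
  switch(method,
         bu = reconcile_bottom_up(base, spec),
         oc = reconcile_oc(base, spec, weights = oc_weights),
         tdfp = reconcile_top_down(top, proportions_fp(base, spec), spec),
         tdha = reconcile_top_down(top, proportions_pha(history, spec),
                                   spec),
         tdhp = reconcile_top_down(
           top, proportions_ahp(history, spec, within = within), spec))
}
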
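#' Declare a strict, balanced forecasting hierarchy
#'
#' A hierarchy is a strict tree of node labels: one root, every other node
#' with exactly one parent, and all leaves at the same depth. Donation data
#' are organised this way (total, then gender, then ABO blood group within
#' gender), and the tree determines how bottom-level series aggregate into
#' every upper-level series.
#'
#' @param children Named list mapping each internal node label to the
#'   character vector of its child labels, e.g.
#'   `list(Total = c("M", "F"), M = c("A_M", ...), F = ...)`.
#'
#' @return An object of class `hierarchy_spec`: a list with `nodes` (all
#'   labels in canonical order: root, then each level left to right),
#'   `parent_of` (named character; `NA` for the root), `level_of` (named
#'   integer; root = 0), and `bottom` (labels of the leaves).
#'
#' @examples
#' spec <- hierarchy_spec(list(Total = c("M", "F"),
#'                             M = c("A_M", "O_M"), F = c("A_F", "O_F")))
#' spec$bottom
#' @export
hierarchy_spec <- function(children) {
  if (!is.list(children) || is.null(names(children)) ||
      any(names(children) == "")) {
    abort("`children` must be a named list of parent -> child labels.",
          class = "donorcast_error_hierarchy")
  }
  parents <- names(children)
  kids <- unlist(children, use.names = FALSE)
  if (!is.character(kids) || anyNA(kids)) {
    abort("Child labels must be character and non-missing.",
          class = "donorcast_error_hierarchy")
  }
  if (anyDuplicated(kids)) {
    abort(
      paste0("Node(s) with multiple parents: ",
             paste(unique(kids[duplicated(kids)]), collapse = ", "),
             ". Only strict trees are supported."),
      class = "donorcast_error_hierarchy")
  }
  roots <- setdiff(parents, kids)
  if (length(roots) != 1L) {
    abort(paste0("Hierarchy must have exactly one root; found: ",
                 if (length(roots)) paste(roots, collapse = ", ") else
                   "none (cycle?)"),
          class = "donorcast_error_hierarchy")
  }
  root <- roots[[1L]]

  parent_of <- stats::setNames(rep(NA_character_, 0L), character())
  for (p in parents) {
    parent_of[children[[p]]] <- p
  }

  # breadth-first walk fixes the canonical node order and detects cycles
  nodes <- character()
  level_of <- integer()
  frontier <- root
  lev <- 0L
  while (length(frontier)) {
    nodes <- c(nodes, frontier)
    level_of[frontier] <- lev
    frontier <- unlist(lapply(frontier, function(p) {
      children[[p]] %||% character()
    }), use.names = FALSE)
    lev <- lev + 1L
    if (lev > length(kids) + 2L) {
      abort("Cycle detected in hierarchy definition.",
            class = "donorcast_error_hierarchy")
    }
  }
  unreached <- setdiff(c(parents, kids), nodes)
  if (length(unreached)) {
    abort(paste0("Node(s) not reachable from the root (cycle?): ",
                 paste(unreached, collapse = ", ")),
          class = "donorcast_error_hierarchy")
  }
  if (anyDuplicated(nodes)) {
    abort("Node labels must be unique.", class = "donorcast_error_hierarchy")
  }

  bottom <- setdiff(nodes, parents)
  if (length(unique(level_of[bottom])) != 1L) {
    abort("All bottom nodes must sit at the same level (balanced tree).",
          class = "donorcast_error_unbalanced")
  }
  # keep bottom in canonical (breadth-first) order
  bottom <- nodes[nodes %in% bottom]

  structure(
    list(nodes = nodes,
         parent_of = parent_of[setdiff(nodes, root)],
         level_of = level_of[nodes],
         bottom = bottom,
         root = root),
    class = "hierarchy_spec")
}

#' @export
print.hierarchy_spec <- function(x, ...) {
  cat("<hierarchy_spec> ", length(x$nodes), " nodes, ",
      max(x$level_of) + 1L, " levels, ", length(x$bottom),
      " bottom series\n", sep = "")
  cat("root:", x$root, "| bottom:", paste(x$bottom, collapse = ", "), "\n")
  invisible(x)
}

#' The gender-by-ABO blood donation hierarchy
#'
#' The two-level tree used throughout: total donations split by donor gender
#' (M, F), each gender split by ABO blood group (A, B, AB, O). Node order is
#' the canonical one (Total; M, F; A_M, B_M, AB_M, O_M, A_F, B_F, AB_F, O_F),
#' which all matrices and output files follow.
#'
#' @return A [hierarchy_spec()] with 11 nodes and 8 bottom series.
#' @examples
#' blood_hierarchy()
#' @export
blood_hierarchy <- function() {
  hierarchy_spec(list(
    Total = c("M", "F"),
    M = c("A_M", "B_M", "AB_M", "O_M"),
    F = c("A_F", "B_F", "AB_F", "O_F")))
}

#' Construct the summing matrix of a hierarchy
#'
#' The summing matrix S is the 0/1 matrix with one row per node and one
#' column per bottom node; `S[r, c] = 1` iff bottom node `c` is `r` itself or
#' a descendant of `r`. Multiplying S by the vector of bottom-level values
#' yields the full coherent vector of node values. For the blood hierarchy S
#' is 11 x 8: an all-ones root row, one row per gender selecting its four
#' blood groups, and an identity block for the bottom nodes.
#'
#' @param spec A [hierarchy_spec()].
#' @return A numeric matrix with node labels as row names and bottom-node
#'   labels as column names, rows in canonical node order.
#' @examples
#' S <- summing_matrix(blood_hierarchy())
#' dim(S)          # 11 x 8
#' colSums(S)      # 3 for every bottom node (itself + parent + root)
#' @export
summing_matrix <- function(spec) {
  stopifnot(inherits(spec, "hierarchy_spec"))
  S <- matrix(0, nrow = length(spec$nodes), ncol = length(spec$bottom),
              dimnames = list(spec$nodes, spec$bottom))
  for (b in spec$bottom) {
    node <- b
    while (!is.na(node)) {
      S[node, b] <- 1
      node <- if (node == spec$root) NA_character_ else spec$parent_of[[node]]
    }
  }
  S
}

#' List the bottom-level descendants of each node
#' @noRd
.descendant_bottoms <- function(spec) {
  S <- summing_matrix(spec)
  lapply(stats::setNames(spec$nodes, spec$nodes),
         function(nd) spec$bottom[S[nd, ] == 1])
}

# ---- long <-> wide conversion helpers ---------------------------------------

#' Convert a long series table to a periods-by-nodes matrix
#' @noRd
.series_matrix <- function(series, nodes = NULL) {
  stopifnot(all(c("period", "node", "value") %in% names(series)))
  wide <- tidyr::pivot_wider(series[c("period", "node", "value")],
                             names_from = "node", values_from = "value")
  wide <- dplyr::arrange(wide, .data$period)
  if (is.null(nodes)) nodes <- setdiff(names(wide), "period")
  missing <- setdiff(nodes, names(wide))
  if (length(missing)) {
    abort(paste0("Series is missing node(s): ",
                 paste(missing, collapse = ", ")),
          class = "donorcast_error_label")
  }
  m <- as.matrix(wide[nodes])
  if (anyNA(m)) {
    abort("Series has missing cells (period x node gaps).",
          class = "donorcast_error_gap")
  }
  rownames(m) <- if (inherits(wide$period, "Date")) {
    format(wide$period, "%Y-%m")
  } else {
    as.character(wide$period)
  }
  attr(m, "periods") <- wide$period
  m
}

#' Convert a periods-by-nodes matrix back to a long tibble
#' @noRd
.series_tibble <- function(m, periods) {
  tibble(period = rep(periods, times = ncol(m)),
         node = rep(colnames(m), each = nrow(m)),
         value = as.vector(m)) %>%
    arrange(.data$period, factor(.data$node, levels = colnames(m))) %>%
    select("period", "node", "value")
}

#' Aggregate bottom-level series up a hierarchy
#'
#' Builds the full coherent set of node series from bottom-level values by
#' applying the summing matrix: each parent equals the sum of its children
#' at every period, by construction.
#'
#' @param bottom A data frame with columns `period`, `node`, `value` holding
#'   the bottom-level series only (all bottom nodes, every period).
#' @param spec A [hierarchy_spec()].
#' @return A tibble `period, node, value` covering every node of the
#'   hierarchy, in canonical node order within each period.
#' @examples
#' spec <- blood_hierarchy()
#' bot <- tibble::tibble(
#'   period = as.Date("2019-01-01"),
#'   node = spec$bottom,
#'   value = c(913, 698, 148, 1906, 721, 544, 116, 1496))
#' aggregate_bottom(bot, spec)
#' @export
aggregate_bottom <- function(bottom, spec) {
  stopifnot(inherits(spec, "hierarchy_spec"))
  m <- .series_matrix(bottom, nodes = spec$bottom)
  extra <- setdiff(unique(bottom$node), spec$bottom)
  if (length(extra)) {
    abort(paste0("Non-bottom node(s) in bottom-level input: ",
                 paste(extra, collapse = ", ")),
          class = "donorcast_error_shape")
  }
  S <- summing_matrix(spec)
  full <- m %*% t(S)              # periods x all-nodes
  .series_tibble(full, attr(m, "periods"))
}

#' Check aggregation coherence of a hierarchical series
#'
#' A hierarchical series is coherent when every upper-level value equals the
#' sum of its bottom-level descendants. This reports, for each upper node,
#' the largest absolute violation of that constraint over all periods.
#'
#' @param series Data frame `period, node, value` covering every node.
#' @param spec A [hierarchy_spec()].
#' @param tol Non-negative tolerance on the absolute violation. Default
#'   `1e-6` (floating-point sums); use `0` for integer-valued series.
#' @return A tibble with one row per upper node: `node`, `max_violation`,
#'   `pass`; the attribute `"pass"` carries the overall verdict, also
#'   returned by [is_coherent()].
#' @examples
#' spec <- blood_hierarchy()
#' x <- simulate_donations(seed = 1)
#' check_coherence(x, spec)
#' @export
check_coherence <- function(series, spec, tol = 1e-6) {
  stopifnot(inherits(spec, "hierarchy_spec"), tol >= 0)
  if (!"period" %in% names(series) && "step" %in% names(series)) {
    series <- dplyr::rename(series, period = "step")
  }
  m <- .series_matrix(series, nodes = spec$nodes)
  S <- summing_matrix(spec)
  upper <- setdiff(spec$nodes, spec$bottom)
  implied <- m[, spec$bottom, drop = FALSE] %*% t(S[upper, , drop = FALSE])
  viol <- abs(m[, upper, drop = FALSE] - implied)
  mv <- unname(apply(viol, 2, max))
  out <- tibble(node = upper, max_violation = mv, pass = mv <= tol)
  attr(out, "pass") <- all(out$pass)
  attr(out, "tol") <- tol
  class(out) <- c("coherence_report", class(out))
  out
}

#' @rdname check_coherence
#' @return `is_coherent()` returns a single logical.
#' @export
is_coherent <- function(series, spec, tol = 1e-6) {
  attr(check_coherence(series, spec, tol), "pass")
}

#' @export
print.coherence_report <- function(x, ...) {
  cat("<coherence_report> tol =", format(attr(x, "tol")),
      if (attr(x, "pass")) "- PASS\n" else "- FAIL\n")
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
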
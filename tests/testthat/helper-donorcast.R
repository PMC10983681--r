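# Shared fixtures, all built in code.

# one parent, two children
pair_spec <- function() hierarchy_spec(list(Total = c("a", "b")))

# root with a single child
chain_spec <- function() hierarchy_spec(list(Total = "X"))

# the Jan-19 bottom-level row of the published out-of-sample forecast table
published_bottom_row <- function() {
  c(A_M = 913, B_M = 698, AB_M = 148, O_M = 1906,
    A_F = 721, B_F = 544, AB_F = 116, O_F = 1496)
}

# long tibble from a periods x nodes matrix of bottom values
bottom_tbl <- function(values, nodes, start = as.Date("2019-01-01")) {
  values <- matrix(values, ncol = length(nodes),
                   dimnames = list(NULL, nodes))
  periods <- seq(start, by = "month", length.out = nrow(values))
  tibble::tibble(
    period = rep(periods, times = ncol(values)),
    node = rep(nodes, each = nrow(values)),
    value = as.vector(values))
}

# base-forecast tibble from a named step x node layout
base_tbl <- function(values_by_node, steps = 1L, model = "test") {
  tibble::tibble(
    node = rep(names(values_by_node), each = length(steps)),
    step = rep(steps, times = length(values_by_node)),
    value = unlist(values_by_node, use.names = FALSE),
    model = model)
}

# random strict 2-level hierarchy: root -> g groups -> leaves per group
random_hierarchy <- function(seed) {
  set.seed(seed)
  g <- sample(2:3, 1)
  per <- sample(2:4, 1)          # balanced: same leaf count per group
  groups <- paste0("g", seq_len(g))
  kids <- lapply(groups, function(gr) paste0(gr, "_", seq_len(per)))
  names(kids) <- groups
  hierarchy_spec(c(list(root = groups), kids))
}

# random positive base forecasts for every node of a hierarchy
random_base <- function(spec, h, seed) {
  set.seed(seed)
  tibble::tibble(
    node = rep(spec$nodes, each = h),
    step = rep(seq_len(h), times = length(spec$nodes)),
    value = stats::runif(h * length(spec$nodes), 10, 100))
}

# random coherent history over a hierarchy
random_history <- function(spec, n, seed) {
  set.seed(seed)
  bottom <- matrix(stats::runif(n * length(spec$bottom), 50, 150),
                   nrow = n, dimnames = list(NULL, spec$bottom))
  aggregate_bottom(bottom_tbl(bottom, spec$bottom), spec)
}

# SARIMA(1,0,0)(1,0,0)[m] simulator with known coefficients
sim_sarima <- function(n, phi, Phi, m = 12, sd = 1, seed) {
  set.seed(seed)
  burn <- 100
  e <- stats::rnorm(n + burn, sd = sd)
  y <- numeric(n + burn)
  for (t in seq_along(y)) {
    y[t] <- e[t] +
      (if (t > 1) phi * y[t - 1] else 0) +
      (if (t > m) Phi * y[t - m] else 0) -
      (if (t > m + 1) phi * Phi * y[t - m - 1] else 0)
  }
  utils::tail(y, n) + 50
}

# orthogonal-projection oracle for optimal combination
pinv_projection <- function(S, yhat) {
  S %*% solve(t(S) %*% S, t(S) %*% yhat)
}
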
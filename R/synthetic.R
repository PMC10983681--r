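#' Configuration for the synthetic donation-series generator
#'
#' Defines the statistical structure of a simulated national blood-bank
#' registry: a gender-by-ABO hierarchy with fixed donor-pool shares, a
#' common multiplicative seasonal pattern with elevated public/school
#' holiday months (April, August, December), a mild linear trend and
#' multiplicative lognormal noise. Defaults mirror the donor-pool
#' composition reported for the Zimbabwean registry: 54% male donors, blood
#' groups O 54% / A 24% / B 18% / AB 4%, and a mean monthly total of about
#' 5265 units.
#'
#' @param n_months Number of monthly periods (default 144 = 12 years).
#' @param start First period, `"YYYY-MM"` (default `"2007-01"`).
#' @param gender_shares Named shares of each gender, summing to 1.
#' @param group_shares Named shares of each ABO group within a gender
#'   (A, B, AB, O order), summing to 1.
#' @param base_monthly_total Expected total donations in a neutral month.
#' @param seasonal_indices 12 multiplicative month factors averaging 1.
#'   Default: +15% in April, August, December, 0.95 elsewhere.
#' @param trend_slope Fractional change per month applied as
#'   `1 + trend_slope * (t - 1)`; default a slight decline (-0.0005).
#' @param noise_sigma Standard deviation of the lognormal noise on the log
#'   scale; draws are mean-1 (`exp(sigma*z - sigma^2/2)`).
#' @return A `synthetic_config` list, validated.
#' @examples
#' synthetic_config(n_months = 24)
#' @export
synthetic_config <- function(n_months = 144L, start = "2007-01",
                             gender_shares = c(M = 0.54, F = 0.46),
                             group_shares = c(A = 0.24, B = 0.18,
                                              AB = 0.04, O = 0.54),
                             base_monthly_total = 5265,
                             seasonal_indices = default_seasonal_indices(),
                             trend_slope = -5e-4, noise_sigma = 0.08) {
  if (abs(sum(gender_shares) - 1) > 1e-9 ||
      abs(sum(group_shares) - 1) > 1e-9) {
    abort("Gender and group shares must each sum to 1.",
          class = "donorcast_error_config")
  }
  if (any(gender_shares <= 0) || any(group_shares <= 0)) {
    abort("Shares must be strictly positive.",
          class = "donorcast_error_config")
  }
  if (length(seasonal_indices) != 12L ||
      abs(mean(seasonal_indices) - 1) > 1e-9 ||
      any(seasonal_indices <= 0)) {
    abort("`seasonal_indices` must be 12 positive factors averaging 1.",
          class = "donorcast_error_config")
  }
  if (n_months < 1 || base_monthly_total <= 0 || noise_sigma < 0) {
    abort("Invalid n_months, base_monthly_total or noise_sigma.",
          class = "donorcast_error_config")
  }
  if (1 + trend_slope * (n_months - 1) <= 0) {
    abort("Trend slope drives values non-positive within the span.",
          class = "donorcast_error_config")
  }
  structure(list(n_months = as.integer(n_months), start = start,
                 gender_shares = gender_shares,
                 group_shares = group_shares,
                 base_monthly_total = base_monthly_total,
                 seasonal_indices = seasonal_indices,
                 trend_slope = trend_slope, noise_sigma = noise_sigma),
            class = "synthetic_config")
}

#' @rdname synthetic_config
#' @export
default_seasonal_indices <- function() {
  s <- rep(0.95, 12)
  s[c(4, 8, 12)] <- 1.15
  s
}

#' Simulate a coherent hierarchical donation series
#'
#' Each bottom-level value is
#' `base_total * gender share * group share * seasonal index(month) *
#' (1 + slope * (t-1)) * noise`, with mean-1 lognormal noise; upper levels
#' are built by aggregation, so the output is coherent by construction and
#' strictly positive. Deterministic given `seed`.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A tibble `period, node, value` over the 11-node
#'   gender-by-ABO hierarchy (values real-valued, not rounded).
#' @examples
#' x <- simulate_donations(seed = 42)
#' is_coherent(x, blood_hierarchy(), tol = 1e-9)
#' @export
simulate_donations <- function(config = synthetic_config(), seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(seed)) set.seed(seed)
  spec <- hierarchy_spec(c(
    list(Total = names(config$gender_shares)),
    lapply(stats::setNames(nm = names(config$gender_shares)), function(g) {
      paste0(names(config$group_shares), "_", g)
    })))
  n <- config$n_months
  start <- as.Date(paste0(config$start, "-01"))
  periods <- seq(start, by = "month", length.out = n)
  month_idx <- as.integer(format(periods, "%m"))
  tt <- seq_len(n)

  shares <- as.vector(outer(config$group_shares, config$gender_shares))
  names(shares) <- spec$bottom
  det <- config$base_monthly_total *
    (config$seasonal_indices[month_idx] * (1 + config$trend_slope * (tt - 1)))
  bottom <- outer(det, shares)          # n x 8 deterministic skeleton
  if (config$noise_sigma > 0) {
    z <- matrix(stats::rnorm(n * length(shares)), nrow = n)
    bottom <- bottom *
      exp(config$noise_sigma * z - config$noise_sigma^2 / 2)
  }
  colnames(bottom) <- spec$bottom
  aggregate_bottom(.series_tibble(bottom, periods), spec)
}

#' Inject a pandemic-style level shift into a series
#'
#' Multiplies every bottom-level value inside the shock window by
#' `1 - magnitude` (a 0.40 magnitude reproduces a 40% collapse in
#' collections) and re-aggregates the upper levels, so coherence is
#' preserved exactly. With `recovery = "linear"` the reduction fades
#' linearly over the window: month `j` of a `duration`-month window is
#' multiplied by `1 - magnitude * (1 - (j-1)/duration)`.
#'
#' @param series Data frame `period, node, value` covering every node.
#' @param spec A [hierarchy_spec()].
#' @param start First shocked period (`Date` or `"YYYY-MM"`).
#' @param duration Number of shocked months.
#' @param magnitude Fractional reduction in `[0, 1)`.
#' @param recovery `"none"` (flat shock) or `"linear"`.
#' @return The shocked series as a coherent tibble `period, node, value`.
#' @examples
#' x <- simulate_donations(seed = 1)
#' xs <- inject_shock(x, blood_hierarchy(), start = "2018-01",
#'                    duration = 6, magnitude = 0.4)
#' @export
inject_shock <- function(series, spec, start, duration,
                         magnitude = 0.40, recovery = c("none", "linear")) {
  recovery <- match.arg(recovery)
  stopifnot(inherits(spec, "hierarchy_spec"))
  if (magnitude < 0 || magnitude >= 1) {
    abort("`magnitude` must be in [0, 1).",
          class = "donorcast_error_config")
  }
  if (is.character(start)) start <- as.Date(paste0(start, "-01"))
  m <- .series_matrix(series, nodes = spec$nodes)
  periods <- attr(m, "periods")
  window <- seq(start, by = "month", length.out = duration)
  if (!all(window %in% periods)) {
    abort("Shock window extends outside the series span.",
          class = "donorcast_error_range")
  }
  idx <- match(window, periods)
  mult <- if (recovery == "linear") {
    1 - magnitude * (1 - (seq_len(duration) - 1) / duration)
  } else {
    rep(1 - magnitude, duration)
  }
  bottom <- m[, spec$bottom, drop = FALSE]
  bottom[idx, ] <- bottom[idx, , drop = FALSE] * mult
  aggregate_bottom(.series_tibble(bottom, periods), spec)
}

#' Descriptive statistics per node
#'
#' Registry-style summary of each bottom-level series: sample size, mean,
#' standard deviation, range, skewness and excess kurtosis (sample
#' versions, `e1071` type 2).
#'
#' @param series Data frame `period, node, value`.
#' @param nodes Node labels to summarise; default every node present,
#'   bottom-first when a `spec` is given.
#' @param spec Optional [hierarchy_spec()]; restricts the default to the
#'   bottom nodes, matching the usual presentation.
#' @return A tibble `node, n, mean, sd, min, max, skew, kurtosis`.
#' @examples
#' donation_summary(simulate_donations(seed = 1), spec = blood_hierarchy())
#' @export
donation_summary <- function(series, nodes = NULL, spec = NULL) {
  if (is.null(nodes)) {
    nodes <- if (!is.null(spec)) spec$bottom else unique(series$node)
  }
  series %>%
    filter(.data$node %in% nodes) %>%
    mutate(node = factor(.data$node, levels = nodes)) %>%
    group_by(.data$node) %>%
    summarise(n = dplyr::n(), mean = mean(.data$value),
              sd = stats::sd(.data$value),
              min = min(.data$value), max = max(.data$value),
              skew = e1071::skewness(.data$value, type = 2),
              kurtosis = e1071::kurtosis(.data$value, type = 2),
              .groups = "drop") %>%
    mutate(node = as.character(.data$node))
}
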
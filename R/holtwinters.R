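#' Fit a Holt-Winters exponential smoothing model
#'
#' Triple exponential smoothing with level, linear trend and a seasonal
#' component, the classical recursions with smoothing parameters
#' alpha (level), beta (trend) and gamma (seasonal), all in \[0, 1\].
#' The seasonal component is multiplicative (indices scale the trend line)
#' or additive (indices shift it); `"auto"` fits both and keeps the one with
#' the smaller AICc computed from the one-step in-sample squared errors.
#' Parameters and initial states are estimated by [stats::HoltWinters()]
#' (bounded L-BFGS-B on the one-step sum of squared errors). The returned
#' state is renormalised — multiplicative seasonal indices average exactly 1
#' (additive: 0) with the level/trend rescaled to compensate — which leaves
#' every forecast unchanged.
#'
#' @param y Numeric series, length at least `2 * season_length`.
#' @param seasonal `"auto"`, `"multiplicative"` or `"additive"`.
#'   Multiplicative mode requires strictly positive observations.
#' @param season_length Season length (months per year: 12).
#' @return A `blood_hw` object with fields `alpha`, `beta`, `gamma`,
#'   `level`, `trend`, `seasonal` (indices for steps 1..s ahead), `mode`,
#'   `sse` and `aicc`. Supports [forecast()], [generics::tidy()],
#'   [generics::glance()].
#' @examples
#' y <- simulate_donations(seed = 1) |> dplyr::filter(node == "Total")
#' fit <- fit_hw(y$value, seasonal = "multiplicative")
#' forecast(fit, 12)
#' @export
fit_hw <- function(y, seasonal = c("auto", "multiplicative", "additive"),
                   season_length = 12L) {
  seasonal <- match.arg(seasonal)
  y <- as.numeric(y)
  m <- as.integer(season_length)
  if (anyNA(y)) abort("Series contains missing values.",
                      class = "donorcast_error_argument")
  if (length(y) < 2L * m) {
    abort(paste0("Holt-Winters needs at least ", 2L * m,
                 " observations; got ", length(y), "."),
          class = "donorcast_error_length")
  }
  if (seasonal == "multiplicative" && any(y <= 0)) {
    abort("Multiplicative seasonality requires strictly positive values.",
          class = "donorcast_error_domain")
  }

  if (stats::sd(y) == 0) {
    mode <- if (seasonal == "auto") "additive" else seasonal
    return(.hw_state(alpha = 0, beta = 0, gamma = 0, level = y[1],
                     trend = 0,
                     seasonal = rep(if (mode == "multiplicative") 1 else 0, m),
                     m = m, mode = mode, sse = 0, aicc = -Inf, y = y,
                     fit = NULL))
  }

  modes <- switch(seasonal,
                  auto = if (all(y > 0)) c("multiplicative", "additive")
                         else "additive",
                  seasonal)
  fits <- lapply(modes, function(mode) {
    tryCatch(suppressWarnings(
      stats::HoltWinters(stats::ts(y, frequency = m), seasonal = mode)),
      error = function(e) NULL)
  })
  names(fits) <- modes
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) {
    abort("Holt-Winters optimisation failed for every seasonal mode.",
          class = "donorcast_error_numerical")
  }
  aiccs <- vapply(fits, .hw_aicc, numeric(1))
  mode <- names(fits)[which.min(aiccs)]
  fit <- fits[[mode]]

  cf <- fit$coefficients
  level <- unname(cf["a"])
  trend <- unname(cf["b"])
  seas <- unname(cf[paste0("s", seq_len(m))])
  # renormalise without changing any forecast
  if (mode == "multiplicative") {
    c0 <- mean(seas)
    seas <- seas / c0
    level <- level * c0
    trend <- trend * c0
  } else {
    c0 <- mean(seas)
    seas <- seas - c0
    level <- level + c0
  }
  .hw_state(alpha = unname(fit$alpha), beta = unname(fit$beta),
            gamma = unname(fit$gamma), level = level, trend = trend,
            seasonal = seas, m = m, mode = mode, sse = fit$SSE,
            aicc = min(aiccs), y = y, fit = fit)
}

.hw_state <- function(alpha, beta, gamma, level, trend, seasonal, m, mode,
                      sse, aicc, y, fit) {
  structure(list(alpha = alpha, beta = beta, gamma = gamma, level = level,
                 trend = trend, seasonal = seasonal, season_length = m,
                 mode = mode, sse = sse, aicc = aicc, y = y, fit = fit),
            class = "blood_hw")
}

# AICc from one-step in-sample errors; k counts the three smoothing
# parameters plus the s + 2 initial states.
.hw_aicc <- function(fit) {
  n <- length(fit$fitted[, "xhat"])
  k <- 3 + stats::frequency(fit$x) + 2
  if (n - k - 1 <= 0) return(Inf)
  n * log(fit$SSE / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' @rdname forecast
#' @export
forecast.blood_hw <- function(object, h, ...) {
  h <- as.integer(h)
  idx <- ((seq_len(h) - 1L) %% object$season_length) + 1L
  base <- object$level + seq_len(h) * object$trend
  if (object$mode == "multiplicative") {
    base * object$seasonal[idx]
  } else {
    base + object$seasonal[idx]
  }
}

#' @export
print.blood_hw <- function(x, ...) {
  cat("<blood_hw> Holt-Winters,", x$mode, "seasonality, s =",
      x$season_length, "\n")
  cat(sprintf("alpha = %.4f, beta = %.4f, gamma = %.4f\n",
              x$alpha, x$beta, x$gamma))
  cat(sprintf("level = %.3f, trend = %.4f\n", x$level, x$trend))
  invisible(x)
}

#' @rdname fit_hw
#' @param x A `blood_hw` object.
#' @param ... Unused.
#' @method tidy blood_hw
#' @export
tidy.blood_hw <- function(x, ...) {
  tibble(term = c("alpha", "beta", "gamma", "level", "trend",
                  paste0("seasonal", seq_along(x$seasonal))),
         estimate = c(x$alpha, x$beta, x$gamma, x$level, x$trend,
                      x$seasonal))
}

#' @rdname fit_hw
#' @method glance blood_hw
#' @export
glance.blood_hw <- function(x, ...) {
  tibble(mode = x$mode, alpha = x$alpha, beta = x$beta, gamma = x$gamma,
         sse = x$sse, aicc = x$aicc, nobs = length(x$y))
}
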
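#' Point forecasts from a fitted model
#'
#' Generic producing `h` deterministic point forecasts from a fitted
#' single-series model ([fit_auto_arima()], [arima_model()], [fit_hw()]).
#'
#' @param object A fitted model object.
#' @param h Forecast horizon (number of steps ahead), `h >= 1`.
#' @param ... Passed to methods.
#' @return A numeric vector of length `h`.
#' @export
forecast <- function(object, h, ...) {
  if (!is.numeric(h) || length(h) != 1L || h < 1) {
    abort("`h` must be a single integer >= 1.",
          class = "donorcast_error_argument")
  }
  UseMethod("forecast")
}

# KPSS level-stationarity statistic with Bartlett/Newey-West long-run
# variance; 5% critical value 0.463. Used only to pick the number of
# ordinary differences.
.kpss_stat <- function(x) {
  n <- length(x)
  e <- x - mean(x)
  s2 <- sum(e^2) / n
  if (s2 <= .Machine$double.eps) return(0)
  l <- trunc(4 * (n / 100)^0.25)
  lrv <- s2
  if (l >= 1) {
    for (k in seq_len(l)) {
      lrv <- lrv + 2 * (1 - k / (l + 1)) *
        sum(e[(k + 1):n] * e[1:(n - k)]) / n
    }
  }
  if (lrv <= 0) lrv <- s2
  sum(cumsum(e)^2) / (n^2 * lrv)
}

.ndiffs <- function(x, max_d) {
  d <- 0L
  while (d < max_d && length(x) > 10 && stats::sd(x) > 0 &&
         .kpss_stat(x) > 0.463) {
    x <- diff(x)
    d <- d + 1L
  }
  d
}

# Seasonal-difference choice via STL seasonal strength:
# strength = max(0, 1 - Var(remainder) / Var(seasonal + remainder)).
.nsdiffs <- function(x, m, max_D) {
  if (max_D < 1L || m < 2L || length(x) < 2 * m + 5) return(0L)
  if (stats::sd(x) == 0) return(0L)
  dec <- tryCatch(stats::stl(stats::ts(x, frequency = m),
                             s.window = "periodic"),
                  error = function(e) NULL)
  if (is.null(dec)) return(0L)
  rem <- dec$time.series[, "remainder"]
  sea <- dec$time.series[, "seasonal"]
  strength <- max(0, 1 - stats::var(rem) / stats::var(sea + rem))
  if (strength >= 0.64) 1L else 0L
}

.arima_ic <- function(fit, ic) {
  k <- length(fit$coef) + 1          # + innovation variance
  n <- fit$nobs
  if (is.na(fit$aic)) return(Inf)
  switch(ic,
         aic = fit$aic,
         bic = fit$aic + k * (log(n) - 2),
         aicc = if (n - k - 1 > 0) fit$aic + 2 * k * (k + 1) / (n - k - 1)
                else Inf)
}

# Reject fits whose expanded AR or MA polynomial has a root on (or
# numerically at) the unit circle.
.roots_ok <- function(fit) {
  ok <- TRUE
  phi <- fit$model$phi
  theta <- fit$model$theta
  if (length(phi) && any(abs(phi) > 1e-8)) {
    ok <- ok && min(Mod(polyroot(c(1, -phi)))) > 1.001
  }
  if (length(theta) && any(abs(theta) > 1e-8)) {
    ok <- ok && min(Mod(polyroot(c(1, theta)))) > 1.001
  }
  ok
}

.fit_candidate <- function(y, p, d, q, P, D, Q, m, include_mean, ic) {
  fit <- tryCatch(
    suppressWarnings(stats::arima(
      y, order = c(p, d, q),
      seasonal = list(order = c(P, D, Q), period = m),
      include.mean = include_mean, method = "CSS-ML",
      optim.control = list(maxit = 1000))),
    error = function(e) NULL)
  if (is.null(fit) || !.roots_ok(fit)) return(list(fit = NULL, ic = Inf))
  list(fit = fit, ic = .arima_ic(fit, ic))
}

#' Fit a seasonal ARIMA model with automatic order selection
#'
#' Selects a (p,d,q)(P,D,Q)[m] model for one node's series. The number of
#' ordinary differences `d` comes from repeated KPSS level-stationarity
#' decisions, the seasonal difference `D` from an STL seasonal-strength
#' heuristic, and (p,q,P,Q) from a stepwise search minimising AICc (an
#' exhaustive grid is available via `stepwise = FALSE`). Models are fitted
#' by [stats::arima()] (CSS-ML); candidates with near-unit AR/MA roots or
#' failed fits are discarded.
#'
#' @param y Numeric series (a plain vector or `ts`).
#' @param seasonal Search seasonal orders? Requires
#'   `length(y) >= 3 * season_length`.
#' @param season_length Season length `m` (months per year: 12).
#' @param max_p,max_q,max_P,max_Q,max_d,max_D Search bounds.
#' @param d,D Fix the differencing orders instead of estimating them.
#' @param stepwise If `FALSE`, search the full order grid.
#' @param ic Information criterion: `"aicc"` (default), `"aic"` or `"bic"`.
#' @return A `blood_arima` object: the selected [stats::arima()] fit plus
#'   the order, the criterion value and the training series. A constant
#'   series yields a degenerate (0,0,0) model whose forecasts equal the
#'   series mean. Supports [forecast()], [generics::tidy()] and
#'   [generics::glance()].
#' @examples
#' y <- simulate_donations(seed = 1) |> dplyr::filter(node == "Total")
#' fit <- fit_auto_arima(y$value)
#' glance(fit)
#' forecast(fit, 12)
#' @export
fit_auto_arima <- function(y, seasonal = TRUE, season_length = 12L,
                           max_p = 3L, max_q = 3L, max_P = 1L, max_Q = 1L,
                           max_d = 2L, max_D = 1L, d = NULL, D = NULL,
                           stepwise = TRUE,
                           ic = c("aicc", "aic", "bic")) {
  ic <- match.arg(ic)
  y <- as.numeric(y)
  if (anyNA(y)) abort("Series contains missing values.",
                      class = "donorcast_error_argument")
  m <- if (seasonal) as.integer(season_length) else 1L
  if (seasonal && length(y) < 3L * m) {
    abort(paste0("Seasonal fitting needs at least ", 3L * m,
                 " observations; got ", length(y), "."),
          class = "donorcast_error_length")
  }
  if (!seasonal && length(y) < 8L) {
    abort("Series too short to fit an ARIMA model.",
          class = "donorcast_error_length")
  }

  if (stats::sd(y) == 0) {
    return(structure(
      list(fit = NULL, order = c(0L, 0L, 0L),
           seasonal_order = c(0L, 0L, 0L), period = m,
           intercept = mean(y), sigma2 = 0, ic = -Inf, ic_type = ic,
           constant = TRUE, y = y),
      class = "blood_arima"))
  }

  if (!seasonal) { max_P <- 0L; max_Q <- 0L; max_D <- 0L }
  if (is.null(D)) D <- .nsdiffs(y, m, max_D)
  D <- min(D, max_D)
  yd <- if (D > 0) diff(y, lag = m, differences = D) else y
  if (is.null(d)) d <- .ndiffs(yd, max_d)
  d <- min(d, max_d)
  include_mean <- (d + D == 0L)

  cache <- new.env(parent = emptyenv())
  eval_one <- function(p, q, P, Q) {
    if (p < 0 || q < 0 || P < 0 || Q < 0 ||
        p > max_p || q > max_q || P > max_P || Q > max_Q) {
      return(Inf)
    }
    key <- paste(p, q, P, Q, sep = "-")
    if (!is.null(cache[[key]])) return(cache[[key]]$ic)
    res <- .fit_candidate(y, p, d, q, P, D, Q, m, include_mean, ic)
    cache[[key]] <- c(res, list(p = p, q = q, P = P, Q = Q))
    res$ic
  }

  if (stepwise) {
    starts <- list(c(2, 2, 1, 1), c(0, 0, 0, 0), c(1, 0, 1, 0),
                   c(0, 1, 0, 1))
    starts <- lapply(starts, function(o) {
      pmin(o, c(max_p, max_q, max_P, max_Q))
    })
    for (o in unique(starts)) eval_one(o[1], o[2], o[3], o[4])
    best <- .best_cached(cache)
    repeat {
      b <- c(best$p, best$q, best$P, best$Q)
      moves <- list(c(1, 0, 0, 0), c(-1, 0, 0, 0), c(0, 1, 0, 0),
                    c(0, -1, 0, 0), c(0, 0, 1, 0), c(0, 0, -1, 0),
                    c(0, 0, 0, 1), c(0, 0, 0, -1), c(1, 1, 0, 0),
                    c(-1, -1, 0, 0), c(1, -1, 0, 0), c(-1, 1, 0, 0),
                    c(0, 0, 1, 1), c(0, 0, -1, -1), c(0, 0, 1, -1),
                    c(0, 0, -1, 1))
      for (mv in moves) {
        o <- b + mv
        eval_one(o[1], o[2], o[3], o[4])
      }
      new_best <- .best_cached(cache)
      if (identical(c(new_best$p, new_best$q, new_best$P, new_best$Q), b)) {
        break
      }
      best <- new_best
    }
  } else {
    for (p in 0:max_p) for (q in 0:max_q)
      for (P in 0:max_P) for (Q in 0:max_Q) eval_one(p, q, P, Q)
    best <- .best_cached(cache)
  }

  if (is.null(best$fit)) {
    # every candidate failed; fall back to a differenced white-noise model
    res <- .fit_candidate(y, 0, d, 0, 0, D, 0, m, include_mean, ic)
    if (is.null(res$fit)) {
      abort("No ARIMA candidate could be fitted.",
            class = "donorcast_error_numerical")
    }
    best <- c(res, list(p = 0, q = 0, P = 0, Q = 0))
  }

  structure(
    list(fit = best$fit, order = c(best$p, d, best$q),
         seasonal_order = c(best$P, D, best$Q), period = m,
         intercept = unname(best$fit$coef["intercept"] %0% NA_real_),
         sigma2 = best$fit$sigma2, ic = best$ic, ic_type = ic,
         constant = FALSE, y = y),
    class = "blood_arima")
}

.best_cached <- function(cache) {
  entries <- as.list(cache)
  ics <- vapply(entries, function(e) e$ic, numeric(1))
  entries[[which.min(ics)]]
}

`%0%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

#' Build an ARIMA model with known coefficients
#'
#' Constructs a fully specified (seasonal) ARIMA model on a given history,
#' without estimating anything: all coefficients are held fixed at the
#' supplied values. Useful for worked examples and for testing forecast
#' recursions against closed forms.
#'
#' @param history Numeric series the forecasts condition on.
#' @param order `c(p, d, q)`.
#' @param seasonal_order `c(P, D, Q)`; default no seasonal part.
#' @param season_length Season length for the seasonal part.
#' @param ar,ma,sar,sma Coefficient vectors of lengths p, q, P, Q.
#' @param intercept Mean term (only when `d + D == 0`); default 0.
#' @return A `blood_arima` object.
#' @examples
#' m <- arima_model(c(1, 3, 2, 8), order = c(1, 0, 0), ar = 0.5)
#' forecast(m, 3)  # 4, 2, 1: geometric decay towards the zero mean
#' @export
arima_model <- function(history, order, seasonal_order = c(0L, 0L, 0L),
                        season_length = 12L, ar = NULL, ma = NULL,
                        sar = NULL, sma = NULL, intercept = 0) {
  stopifnot(length(order) == 3L, length(seasonal_order) == 3L)
  p <- order[1]; d <- order[2]; q <- order[3]
  P <- seasonal_order[1]; D <- seasonal_order[2]; Q <- seasonal_order[3]
  stopifnot(length(ar %||% numeric()) == p,
            length(ma %||% numeric()) == q,
            length(sar %||% numeric()) == P,
            length(sma %||% numeric()) == Q)
  include_mean <- (d + D == 0L)
  fixed <- c(ar, ma, sar, sma, if (include_mean) intercept)
  fit <- suppressWarnings(stats::arima(
    as.numeric(history), order = c(p, d, q),
    seasonal = list(order = c(P, D, Q), period = season_length),
    include.mean = include_mean,
    fixed = if (length(fixed)) fixed else NULL,
    transform.pars = FALSE))
  structure(
    list(fit = fit, order = c(p, d, q), seasonal_order = c(P, D, Q),
         period = season_length,
         intercept = if (include_mean) intercept else NA_real_,
         sigma2 = fit$sigma2, ic = NA_real_, ic_type = NA_character_,
         constant = FALSE, y = as.numeric(history)),
    class = "blood_arima")
}

#' @rdname forecast
#' @export
forecast.blood_arima <- function(object, h, ...) {
  h <- as.integer(h)
  if (object$constant) return(rep(object$intercept, h))
  as.numeric(stats::predict(object$fit, n.ahead = h)$pred)
}

#' @export
print.blood_arima <- function(x, ...) {
  cat("<blood_arima> ARIMA(", paste(x$order, collapse = ","), ")",
      if (x$period > 1) paste0("(", paste(x$seasonal_order, collapse = ","),
                               ")[", x$period, "]"),
      if (x$constant) " [constant series]", "\n", sep = "")
  if (!is.null(x$fit) && length(x$fit$coef)) {
    print(round(x$fit$coef, 4))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_auto_arima
#' @param x A `blood_arima` object.
#' @param ... Unused.
#' @method tidy blood_arima
#' @export
tidy.blood_arima <- function(x, ...) {
  if (is.null(x$fit) || !length(x$fit$coef)) {
    return(tibble(term = character(), estimate = numeric(),
                  std.error = numeric()))
  }
  se <- sqrt(pmax(diag(x$fit$var.coef), 0))
  se <- se[names(x$fit$coef)]
  tibble(term = names(x$fit$coef),
         estimate = unname(x$fit$coef),
         std.error = unname(se))
}

#' @rdname fit_auto_arima
#' @method glance blood_arima
#' @export
glance.blood_arima <- function(x, ...) {
  tibble(order = paste0("(", paste(x$order, collapse = ","), ")(",
                        paste(x$seasonal_order, collapse = ","), ")[",
                        x$period, "]"),
         sigma2 = x$sigma2,
         ic = x$ic, ic_type = x$ic_type,
         nobs = length(x$y))
}
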
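#' Fit a polynomial trend to a time series
#'
#' Least-squares polynomial of the requested degree. The time axis is
#' affinely mapped to `[-1, 1]` over the training range before fitting —
#' a raw high-degree fit on day identifiers in the hundreds is numerically
#' explosive, and the mapping leaves the fitted polynomial unchanged as a
#' function of `t`. The mapping is stored in the model and reused by
#' [eval_trend()], including for extrapolation beyond the training range.
#'
#' @param series A [season_series()] or data frame with columns `t`, `y`.
#' @param degree Polynomial degree, `>= 0`; default 9.
#' @return An object of class `trend_model` with elements `degree`,
#'   `coefficients` (a0..a_degree on the scaled axis), `center`, `scale`.
#' @export
fit_trend <- function(series, degree = 9L) {
  series <- as_season_series(series)
  degree <- as.integer(degree)
  if (degree < 0L) stop("'degree' must be >= 0")
  m <- nrow(series)
  if (m <= degree)
    stop(sprintf("need more than degree = %d observations to fit the trend (got %d)",
                 degree, m))
  center <- (min(series$t) + max(series$t)) / 2
  scale <- (max(series$t) - min(series$t)) / 2
  if (scale == 0) scale <- 1
  u <- (series$t - center) / scale
  X <- outer(u, 0:degree, `^`)
  fit <- stats::lm.fit(X, series$y)
  co <- fit$coefficients
  if (anyNA(co)) {
    warning(sprintf("rank-deficient trend fit: effective degree reduced (%d aliased terms set to 0)",
                    sum(is.na(co))))
    co[is.na(co)] <- 0
  }
  structure(list(degree = degree, coefficients = unname(co),
                 center = center, scale = scale),
            class = "trend_model")
}

#' Evaluate a fitted polynomial trend
#'
#' Horner evaluation at arbitrary times using the stored axis mapping;
#' extrapolation outside the training range is permitted.
#'
#' @param model A `trend_model` from [fit_trend()].
#' @param t Numeric vector of times (progressive day ids).
#' @export
eval_trend <- function(model, t) {
  stopifnot(inherits(model, "trend_model"))
  u <- (t - model$center) / model$scale
  out <- rep(0, length(u))
  for (a in rev(model$coefficients)) out <- out * u + a
  out
}

#' @export
print.trend_model <- function(x, ...) {
  cat(sprintf("polynomial trend, degree %d (time axis centred at %g, half-range %g)\n",
              x$degree, x$center, x$scale))
  print(stats::setNames(x$coefficients, paste0("a", seq_along(x$coefficients) - 1)))
  invisible(x)
}

#' Remove a fitted trend from a series
#'
#' Elementwise `y(i) - trend(t(i))`, yielding the de-trended series whose
#' seasonal fluctuation the F1 regression models.
#'
#' @inheritParams fit_trend
#' @param model A `trend_model`.
#' @return A `season_series` with `y` replaced by the residual.
#' @export
detrend <- function(series, model) {
  series <- as_season_series(series)
  out <- series
  out$y <- series$y - eval_trend(model, series$t)
  out
}
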
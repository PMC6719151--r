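#' Forecast accuracy report
#'
#' The four indices used to judge seasonal forecasts, with
#' `e = predicted - actual`:
#' * RMSE `= sqrt(mean(e^2))`
#' * MAPE `= 100 * mean(|e / actual|)` (percent; undefined if any actual
#'   is 0)
#' * MAD  `= mean(|e|)`
#' * MAD-MEAN `= 100 * sum(|e|) / sum(actual)` (percent; undefined if the
#'   actuals sum to 0) — the same statistic that drives the node-search
#'   stopping rule in [fit_season()].
#'
#' @param actual,predicted Equal-length numeric vectors.
#' @return An object of class `accuracy_report` with elements `rmse`,
#'   `mape`, `mad`, `mad_mean`, `n`. Undefined indices are `NA` with a
#'   warning; the others are still returned.
#' @examples
#' accuracy_report(c(10, 20, 30), c(11, 19, 33))
#' @export
accuracy_report <- function(actual, predicted) {
  if (length(actual) != length(predicted))
    stop("'actual' and 'predicted' must have the same length")
  if (length(actual) == 0L) stop("need at least one pair")
  if (anyNA(actual) || anyNA(predicted)) stop("inputs must not contain NA")
  e <- predicted - actual
  mape <- if (any(actual == 0)) {
    warning("MAPE undefined: at least one actual value is 0")
    NA_real_
  } else 100 * mean(abs(e / actual))
  mm <- mad_mean_pct(actual, predicted)
  if (is.na(mm)) warning("MAD-MEAN undefined: actual values sum to 0")
  structure(list(rmse = sqrt(mean(e^2)), mape = mape, mad = mean(abs(e)),
                 mad_mean = mm, n = length(actual)),
            class = "accuracy_report")
}

# Single source of truth for the MAD-MEAN index (percent); also used by
# the seasonal node search. NA when the denominator vanishes.
mad_mean_pct <- function(actual, predicted) {
  s <- sum(actual)
  if (s == 0) return(NA_real_)
  100 * sum(abs(predicted - actual)) / s
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("   RMSE    MAPE     MAD MAD-MEAN   (n = %d)\n", x$n))
  cat(sprintf("%7.4g %7.4g %7.4g %8.4g\n", x$rmse, x$mape, x$mad, x$mad_mean))
  invisible(x)
}
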
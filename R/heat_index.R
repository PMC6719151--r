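#' Rothfusz heat-index regression coefficients
#'
#' The standard NWS/Rothfusz 9-term multiple-regression coefficients for
#' the heat index, in degrees Fahrenheit. Any sign in the published
#' formula is folded into the coefficient value, so evaluation is a plain
#' signed sum over the terms
#' `1, T, RH, T*RH, T^2, RH^2, T^2*RH, T*RH^2, T^2*RH^2`.
#'
#' @param values Optional replacement vector of 9 coefficients.
#' @param units `"fahrenheit"` (default) or `"celsius"`: the temperature
#'   unit in which the regression is evaluated.
#' @return An object of class `hi_coefficients`.
#' @export
hi_coefficients <- function(values = NULL, units = c("fahrenheit", "celsius")) {
  units <- match.arg(units)
  if (is.null(values))
    values <- c(-42.379, 2.04901523, 10.14333127, -0.22475541,
                -0.00683783, -0.05481717, 0.00122874, 0.00085282,
                -0.00000199)
  if (length(values) != 9L || anyNA(values))
    stop("a heat-index coefficient set has exactly 9 finite values")
  structure(list(values = as.numeric(values), units = units),
            class = "hi_coefficients")
}

#' Heat index from temperature and relative humidity
#'
#' Apparent-temperature measure of physiological heat stress. For
#' temperatures above 27 degrees C with relative humidity above 40% the
#' 9-term regression is evaluated (by default the NWS/Rothfusz set, in
#' Fahrenheit: input is converted degrees C to F, evaluated, and converted back);
#' everywhere else the heat index is taken equal to the air temperature.
#' The rule is applied exactly at the stated boundary: the regression is
#' used iff `T > 27 & rh > 40`, so the piecewise hand-off is not
#' continuous.
#'
#' @param temp_c Air temperature in degrees C (daily maximum in the intended
#'   use); must lie in a physically plausible -50..60 degrees C.
#' @param rh Relative humidity in percent, in `[0, 100]`.
#' @param coefficients A [hi_coefficients()] set.
#' @return Heat index in degrees C, same length as the inputs.
#' @examples
#' heat_index(20, 20)          # passthrough: 20
#' heat_index(32.2, 70)        # regression region: about 40.9 degrees C
#' @export
heat_index <- function(temp_c, rh, coefficients = hi_coefficients()) {
  stopifnot(inherits(coefficients, "hi_coefficients"))
  if (length(temp_c) != length(rh))
    stop("'temp_c' and 'rh' must have the same length")
  bad <- which(!is.finite(rh) | rh < 0 | rh > 100)
  if (length(bad))
    stop(sprintf("relative humidity outside [0, 100] at position(s) %s",
                 paste(utils::head(bad, 5L), collapse = ", ")))
  bad <- which(!is.finite(temp_c) | temp_c < -50 | temp_c > 60)
  if (length(bad))
    stop(sprintf("temperature outside plausible -50..60 C at position(s) %s",
                 paste(utils::head(bad, 5L), collapse = ", ")))
  out <- temp_c
  reg <- temp_c > 27 & rh > 40
  if (any(reg)) {
    Tr <- if (coefficients$units == "fahrenheit") temp_c[reg] * 9 / 5 + 32 else temp_c[reg]
    H <- rh[reg]
    cf <- coefficients$values
    hi <- cf[1] + cf[2] * Tr + cf[3] * H + cf[4] * Tr * H + cf[5] * Tr^2 +
      cf[6] * H^2 + cf[7] * Tr^2 * H + cf[8] * Tr * H^2 + cf[9] * Tr^2 * H^2
    out[reg] <- if (coefficients$units == "fahrenheit") (hi - 32) * 5 / 9 else hi
  }
  out
}

#' Daily heat-index series from weather records
#'
#' Applies [heat_index()] row by row to a daily weather table, preserving
#' gaps. Rows whose temperature falls between the regression guard and
#' the low-temperature/low-humidity region described for passthrough
#' (25 <= T <= 27 degrees C, or RH between 30% and 40%) are still passed
#' through unchanged; their count is reported in a message.
#'
#' @param weather Data frame with columns `t` (or `date`), `tmax_c`,
#'   `rh_pct`, time-ordered.
#' @param coefficients A [hi_coefficients()] set.
#' @param season_length Passed through to the output [season_series()]
#'   when `t` is a progressive day id.
#' @return A [season_series()] of heat-index values (column `y`), or a
#'   data frame `(date, hi_c)` when the input is dated.
#' @export
hi_series <- function(weather, coefficients = hi_coefficients(),
                      season_length = 62L) {
  if (!is.data.frame(weather) || !all(c("tmax_c", "rh_pct") %in% names(weather)))
    stop("'weather' needs columns 'tmax_c' and 'rh_pct' plus 't' or 'date'")
  hi <- tryCatch(
    heat_index(weather$tmax_c, weather$rh_pct, coefficients),
    error = function(e) stop(sprintf("weather table invalid: %s", conditionMessage(e))))
  gap <- sum(!(weather$tmax_c > 27 & weather$rh_pct > 40) &
               !(weather$tmax_c < 25 & weather$rh_pct < 30))
  if (gap > 0)
    message(sprintf("%d row(s) in the applicability gap region passed through as HI = T", gap))
  if ("t" %in% names(weather)) {
    season_series(weather$t, hi, season_length)
  } else if ("date" %in% names(weather)) {
    data.frame(date = weather$date, hi_c = hi)
  } else stop("'weather' needs a 't' or 'date' column")
}
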
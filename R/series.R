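#' Seasonal day series
#'
#' The time-series container used throughout the package: a data frame
#' with a strictly increasing progressive day identifier `t`, the observed
#' value `y`, and calendar metadata derived from the seasonal layout —
#' `year` (1-based index of the seasonal window) and `phase` (day-of-season
#' in `1..season_length`). The progressive identifier concatenates the
#' yearly seasonal windows, so `t = (year - 1) * season_length + phase`;
#' missing days are simply absent rows.
#'
#' @param t Strictly increasing numeric vector of progressive day ids.
#' @param y Observed values, same length as `t`, no `NA`.
#' @param season_length Days per seasonal window (default 62, a July +
#'   August window).
#' @return A data frame of class `season_series` with columns `t`, `y`,
#'   `year`, `phase` and attribute `season_length`.
#' @export
season_series <- function(t, y, season_length = 62L) {
  if (length(t) != length(y)) stop("'t' and 'y' must have the same length")
  if (anyNA(t) || anyNA(y)) stop("'t' and 'y' must not contain NA")
  if (length(t) > 1L && any(diff(t) <= 0))
    stop("'t' must be strictly increasing")
  season_length <- as.integer(season_length)
  if (season_length < 1L) stop("'season_length' must be a positive integer")
  phase <- ((t - 1) %% season_length) + 1
  year <- ((t - 1) %/% season_length) + 1
  out <- data.frame(t = t, y = y, year = year, phase = phase)
  attr(out, "season_length") <- season_length
  class(out) <- c("season_series", "data.frame")
  out
}

#' @export
print.season_series <- function(x, ...) {
  cat(sprintf("season_series: %d observations, season length %d days, %d year window(s)\n",
              nrow(x), attr(x, "season_length"),
              if (nrow(x)) max(x$year) else 0L))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

as_season_series <- function(x, season_length = 62L) {
  if (inherits(x, "season_series")) return(x)
  if (is.data.frame(x)) {
    if (!all(c("t", "y") %in% names(x)))
      stop("a series data frame needs columns 't' and 'y'")
    return(season_series(x$t, x$y, season_length))
  }
  stop("cannot interpret 'x' as a season_series")
}
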
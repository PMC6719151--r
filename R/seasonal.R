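#' Assign seasonal subsets by day-of-season phase
#'
#' Splits the `season_length` phases into `S` contiguous blocks of width
#' `ceiling(season_length / S)`, with the final block absorbing the
#' remainder (e.g. a 62-day window with `S = 9` gives eight 7-day blocks
#' and one 6-day block): `s = min(ceiling(phase / width), S)`.
#'
#' @param series A [season_series()].
#' @param S Number of seasonal subsets.
#' @param season_length Days per seasonal window; defaults to the series'
#'   own attribute.
#' @return The series with an added integer column `season`.
#' @export
assign_seasons <- function(series, S, season_length = attr(series, "season_length")) {
  series <- as_season_series(series, season_length)
  S <- as.integer(S)
  if (S < 1L) stop("'S' must be >= 1")
  if (season_length < S) stop("'season_length' must be >= S")
  if (any(series$phase < 1 | series$phase > season_length))
    stop("phases must lie in 1..season_length")
  series$season <- season_of_phase(series$phase, S, season_length)
  series
}

season_of_phase <- function(phase, S, season_length) {
  width <- ceiling(season_length / S)
  pmin(ceiling(phase / width), S)
}

#' Phase-block widths of the seasonal split
#'
#' @inheritParams assign_seasons
#' @return Integer vector of `S` block widths summing to `season_length`.
#' @export
season_block_widths <- function(S, season_length) {
  tabulate(season_of_phase(seq_len(season_length), S, season_length), S)
}

#' Fit the F1 seasonal regression for one subset
#'
#' Runs the adaptive node search on the de-trended observations of one
#' phase block, pooled across years. Starting from `n = n_min` (default 3)
#' nodes on the observed phase range, each pass builds the h-uniform
#' raised-cosine partition, checks sufficient density, computes the F1
#' components, and evaluates the MAD-MEAN of the fit; the search accepts
#' the first node count whose MAD-MEAN falls at or below `threshold`
#' (`stop_reason = "threshold_met"`). If density fails the previous
#' pass is returned (`"density_limit"`); if the node cap is reached
#' without meeting the threshold the cap's fit is returned
#' (`"nmax_reached"`); a subset with fewer than 3 distinct phases gets a
#' constant fit at the subset mean (`"degenerate"`).
#'
#' MAD-MEAN is computed with the raw (not de-trended) values in the
#' denominator: the trend cancels in the residual, so the index equals
#' the percent ratio of summed absolute fit errors to the summed raw
#' series — the scale on which the stopping threshold is meaningful.
#'
#' @param phase Day-of-season phases of the subset's observations.
#' @param y De-trended values.
#' @param y0 Raw values for the same observations (MAD-MEAN denominator).
#' @param threshold MAD-MEAN acceptance threshold (percent), `> 0`.
#' @param n_min,n_max Node-search limits; `n_max` defaults to the number
#'   of distinct phases in the subset.
#' @return An object of class `season_fit`: `domain`, `partition`,
#'   `components`, `n`, `mad_mean`, `stop_reason`, and the per-iteration
#'   search `trace` (columns `n`, `mad_mean`).
#' @export
fit_season <- function(phase, y, y0, threshold, n_min = 3L, n_max = NULL) {
  if (length(phase) == 0L) stop("empty seasonal subset")
  if (length(phase) != length(y) || length(phase) != length(y0))
    stop("'phase', 'y' and 'y0' must have the same length")
  if (!is.numeric(threshold) || threshold <= 0) stop("'threshold' must be > 0")
  n_min <- max(3L, as.integer(n_min))
  q <- length(unique(phase))
  if (is.null(n_max)) n_max <- q
  n_max <- max(n_min, as.integer(n_max))

  degenerate <- function() {
    structure(list(
      domain = range(phase), partition = NULL,
      components = structure(list(c0 = mean(y), c1 = 0), class = "f1_components"),
      n = 1L, mad_mean = mad_mean_pct(y0, y0 + (mean(y) - y)),
      stop_reason = "degenerate",
      trace = data.frame(n = integer(), mad_mean = numeric())), class = "season_fit")
  }
  if (q < 3L) return(degenerate())

  dom <- range(phase)
  trace <- data.frame(n = integer(), mad_mean = numeric())
  accepted <- NULL
  reason <- "nmax_reached"
  for (n in n_min:n_max) {
    P <- fuzzy_partition(dom[1], dom[2], n)
    if (!is_sufficiently_dense(P, phase)$dense) {
      reason <- "density_limit"
      break
    }
    comps <- f1_transform(P, phase, y)
    fit <- inverse_f1_transform(P, comps, phase)
    # residual fit - y equals (fit + trend) - y0, so the raw-denominator
    # index is computed from the raw values directly
    mm <- mad_mean_pct(y0, y0 + (fit - y))
    trace <- rbind(trace, data.frame(n = n, mad_mean = mm))
    accepted <- list(partition = P, components = comps, n = n, mad_mean = mm)
    if (!is.na(mm) && mm <= threshold) {
      reason <- "threshold_met"
      break
    }
  }
  if (is.null(accepted)) return(degenerate())  # n_min already non-dense
  structure(list(domain = dom, partition = accepted$partition,
                 components = accepted$components, n = accepted$n,
                 mad_mean = accepted$mad_mean, stop_reason = reason,
                 trace = trace),
            class = "season_fit")
}

#' @export
print.season_fit <- function(x, ...) {
  cat(sprintf("season fit on phases [%g, %g]: n = %d, MAD-MEAN = %s%%, stop: %s\n",
              x$domain[1], x$domain[2], x$n,
              formatC(x$mad_mean, digits = 4, format = "g"), x$stop_reason))
  invisible(x)
}

#' Fit the TSSF1 seasonal forecaster
#'
#' The full pipeline: fit a polynomial trend on the progressive day axis,
#' subtract it, split the de-trended observations into `S` phase blocks,
#' and fit each block's fluctuation with the adaptive F1 regression of
#' [fit_season()]. The fitted model forecasts with
#' `y_hat(t) = f1_s(phase(t)) + trend(t)`.
#'
#' @param series A [season_series()] or data frame with columns `t`, `y`.
#' @param degree Trend polynomial degree (default 9).
#' @param S Number of seasonal subsets (default 9, weekly blocks of a
#'   62-day window).
#' @param season_length Days per seasonal window (default 62).
#' @param threshold MAD-MEAN stopping threshold in percent (default 5).
#' @param n_min,n_max Node-search limits passed to [fit_season()].
#' @return An object of class `tssf1_model`.
#' @examples
#' sim <- generate_series(sim_config(years = 4, seed = 42))
#' fit <- fit_tssf1(sim$series, degree = 2)
#' fit
#' predict(fit, t = 249:260)
#' @export
fit_tssf1 <- function(series, degree = 9L, S = 9L, season_length = 62L,
                      threshold = 5, n_min = 3L, n_max = NULL) {
  series <- as_season_series(series, season_length)
  if (nrow(series) == 0L) stop("empty series")
  trend <- fit_trend(series, degree)
  det <- detrend(series, trend)
  det <- assign_seasons(det, S, season_length)
  seasons <- vector("list", S)
  for (s in seq_len(S)) {
    rows <- det$season == s
    if (!any(rows)) {
      seasons[[s]] <- structure(list(
        domain = phase_block_range(s, S, season_length), partition = NULL,
        components = structure(list(c0 = 0, c1 = 0), class = "f1_components"),
        n = 0L, mad_mean = NA_real_, stop_reason = "degenerate",
        trace = data.frame(n = integer(), mad_mean = numeric())),
        class = "season_fit")
    } else {
      seasons[[s]] <- fit_season(det$phase[rows], det$y[rows],
                                 series$y[rows], threshold, n_min, n_max)
    }
  }
  structure(list(trend = trend, seasons = seasons, S = as.integer(S),
                 season_length = as.integer(season_length),
                 config = list(degree = as.integer(degree), threshold = threshold,
                               n_min = as.integer(n_min), n_max = n_max)),
            class = "tssf1_model")
}

phase_block_range <- function(s, S, season_length) {
  ph <- which(season_of_phase(seq_len(season_length), S, season_length) == s)
  range(ph)
}

#' @export
print.tssf1_model <- function(x, ...) {
  cat(sprintf("TSSF1 model: trend degree %d, %d seasonal subsets over a %d-day window, threshold %g%%\n",
              x$trend$degree, x$S, x$season_length, x$config$threshold))
  tab <- data.frame(
    season = seq_len(x$S),
    phases = vapply(x$seasons, function(s) paste(s$domain, collapse = "-"), ""),
    n = vapply(x$seasons, function(s) s$n, 0L),
    mad_mean = vapply(x$seasons, function(s) s$mad_mean, 0),
    stop = vapply(x$seasons, function(s) s$stop_reason, ""))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Forecast from a fitted TSSF1 model
#'
#' `y_hat(t) = f1_s(phase(t)) + trend(t)`: the seasonal term is the
#' stored inverse F1-transform of the phase block containing the
#' day-of-season phase of `t` (a function of phase only, so the same
#' phase in different years differs exactly by the trend), plus the
#' polynomial trend evaluated at `t`. Phases outside a season's fitted
#' domain (possible with missing training days) are clamped to the
#' domain; degenerate seasons contribute their constant.
#'
#' @param object A `tssf1_model`.
#' @param t Numeric vector of progressive day ids to forecast.
#' @param ... Unused.
#' @return Numeric vector of forecasts, one per element of `t`.
#' @export
predict.tssf1_model <- function(object, t, ...) {
  phase <- ((t - 1) %% object$season_length) + 1
  if (any(phase < 1 | phase > object$season_length))
    stop("day-of-season phase outside 1..season_length")
  s_idx <- season_of_phase(phase, object$S, object$season_length)
  seasonal <- numeric(length(t))
  for (s in unique(s_idx)) {
    sel <- s_idx == s
    sf <- object$seasons[[s]]
    if (is.null(sf$partition)) {
      seasonal[sel] <- sf$components$c0
    } else {
      d <- pmin(pmax(phase[sel], sf$domain[1]), sf$domain[2])
      seasonal[sel] <- inverse_f1_transform(sf$partition, sf$components, d)
    }
  }
  seasonal + eval_trend(object$trend, t)
}

#' Forecast a contiguous range of days
#'
#' Vectorised convenience wrapper around [predict.tssf1_model()] for a
#' closed range of progressive day ids.
#'
#' @param model A `tssf1_model`.
#' @param t_start,t_end First and last day id (inclusive); an empty range
#'   (`t_end < t_start`) yields an empty series.
#' @return A [season_series()] of predictions.
#' @export
forecast_range <- function(model, t_start, t_end) {
  stopifnot(inherits(model, "tssf1_model"))
  if (t_end < t_start)
    return(season_series(numeric(0), numeric(0), model$season_length))
  t <- seq(t_start, t_end)
  season_series(t, predict(model, t), model$season_length)
}
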
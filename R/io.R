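#' Read a univariate time series from CSV
#'
#' Accepts two-column CSV `(date-or-dayid, value)` with a header. When
#' the first column holds integer day identifiers they are used as the
#' progressive day axis directly. When it holds ISO-8601 dates, each
#' year's seasonal window is anchored at `window_start` (month-day, e.g.
#' `"07-01"` for a July-August window; default: the earliest month-day
#' present in the data) and the progressive id is derived as
#' `(year index - 1) * season_length + day offset + 1`; dates falling
#' outside the window are dropped with a warning. Out-of-order rows are
#' sorted with a warning; duplicate time points are an error.
#'
#' @param path CSV file path.
#' @param season_length Days per seasonal window (default 62).
#' @param window_start Optional `"MM-DD"` anchor of the seasonal window.
#' @return A [season_series()].
#' @export
read_timeseries_csv <- function(path, season_length = 62L, window_start = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop(sprintf("'%s': need two columns (time, value)", path))
  tm_raw <- df[[1L]]
  val <- suppressWarnings(as.numeric(df[[2L]]))
  if (anyNA(val))
    stop(sprintf("'%s': unparseable value(s) at data row(s) %s", path,
                 paste(utils::head(which(is.na(val)), 5L), collapse = ", ")))
  num <- suppressWarnings(as.numeric(tm_raw))
  if (!anyNA(num) && all(num == round(num))) {
    t <- num
  } else {
    d <- as.Date(tm_raw)
    if (anyNA(d))
      stop(sprintf("'%s': unparseable date(s) at data row(s) %s", path,
                   paste(utils::head(which(is.na(d)), 5L), collapse = ", ")))
    if (is.null(window_start)) {
      md <- format(d, "%m-%d")
      window_start <- min(md)
    }
    anchor <- as.Date(paste0(format(d, "%Y"), "-", window_start))
    offset <- as.integer(d - anchor)
    ok <- offset >= 0L & offset < season_length
    if (any(!ok)) {
      warning(sprintf("%d row(s) outside the %d-day window starting %s were dropped",
                      sum(!ok), season_length, window_start))
      d <- d[ok]; val <- val[ok]; offset <- offset[ok]
    }
    yrs <- as.integer(format(d, "%Y"))
    t <- (yrs - min(yrs)) * as.integer(season_length) + offset + 1
  }
  if (anyDuplicated(t)) stop(sprintf("'%s': duplicate time points", path))
  if (is.unsorted(t)) {
    warning(sprintf("'%s': rows were out of order and have been sorted", path))
    o <- order(t); t <- t[o]; val <- val[o]
  }
  season_series(t, val, season_length)
}

#' Write a series to CSV
#'
#' Two columns `t,y`; the inverse of [read_timeseries_csv()] for day-id
#' input.
#'
#' @param series A [season_series()] or data frame with `t`, `y`.
#' @param path Output path.
#' @export
write_timeseries_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series)[, c("t", "y")], path, row.names = FALSE)
  invisible(path)
}

#' Read a daily weather CSV
#'
#' Columns `date` (ISO-8601) or `t` (day id), `tmax_c`, `rh_pct`.
#'
#' @param path CSV file path.
#' @return Data frame suitable for [hi_series()].
#' @export
read_weather_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tmax_c", "rh_pct")
  if (!all(need %in% names(df)) || !any(c("t", "date") %in% names(df)))
    stop(sprintf("'%s': need columns (t or date), tmax_c, rh_pct", path))
  df
}

#' Serialise a fitted TSSF1 model to JSON
#'
#' Writes trend coefficients and axis mapping, the seasonal layout, the
#' config snapshot, and per-season node counts, partitions and F1
#' components — everything needed to reload and predict identically.
#'
#' @param model A `tssf1_model`.
#' @param path Output JSON path.
#' @export
write_tssf1_json <- function(model, path) {
  stopifnot(inherits(model, "tssf1_model"))
  seasons <- lapply(seq_along(model$seasons), function(s) {
    sf <- model$seasons[[s]]
    list(season = s, domain = sf$domain, n = sf$n,
         nodes = if (is.null(sf$partition)) NULL else sf$partition$nodes,
         c0 = sf$components$c0, c1 = sf$components$c1,
         mad_mean = sf$mad_mean, stop_reason = sf$stop_reason)
  })
  obj <- list(package = "ftsf", model = "tssf1",
              trend = model$trend[c("degree", "coefficients", "center", "scale")],
              S = model$S, season_length = model$season_length,
              config = model$config, seasons = seasons)
  # 17 significant digits: doubles round-trip exactly, so a reloaded
  # model predicts identically
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' Reload a TSSF1 model from JSON
#'
#' @param path JSON file written by [write_tssf1_json()].
#' @return A `tssf1_model` whose predictions match the original.
#' @export
read_tssf1_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$model, "tssf1")) stop(sprintf("'%s' is not a TSSF1 model file", path))
  trend <- structure(list(degree = as.integer(obj$trend$degree),
                          coefficients = as.numeric(obj$trend$coefficients),
                          center = obj$trend$center, scale = obj$trend$scale),
                     class = "trend_model")
  mk_season <- function(row) {
    part <- if (is.null(row$nodes) || length(row$nodes) < 3L) NULL else
      fuzzy_partition(row$domain[1], row$domain[2], length(row$nodes))
    structure(list(domain = as.numeric(row$domain), partition = part,
                   components = structure(list(c0 = as.numeric(row$c0),
                                               c1 = as.numeric(row$c1)),
                                          class = "f1_components"),
                   n = as.integer(row$n),
                   mad_mean = if (is.null(row$mad_mean)) NA_real_ else row$mad_mean,
                   stop_reason = row$stop_reason,
                   trace = data.frame(n = integer(), mad_mean = numeric())),
              class = "season_fit")
  }
  seasons <- if (is.data.frame(obj$seasons)) {
    lapply(seq_len(nrow(obj$seasons)), function(i) mk_season(
      lapply(obj$seasons, function(col) if (is.list(col)) col[[i]] else col[i])))
  } else lapply(obj$seasons, mk_season)
  structure(list(trend = trend, seasons = seasons, S = as.integer(obj$S),
                 season_length = as.integer(obj$season_length),
                 config = obj$config),
            class = "tssf1_model")
}
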
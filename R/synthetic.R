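#' Mean-zero weekly fluctuation profile
#'
#' A sinusoidal day-of-season profile with a weekly period, centred to
#' mean zero over the window — the default stand-in for the repeating
#' within-season pattern of a summer weather series.
#'
#' @param season_length Days per seasonal window.
#' @param amplitude Peak amplitude before centring (default 2).
#' @param period Fluctuation period in days (default 7).
#' @return Numeric vector of length `season_length` with mean 0.
#' @export
weekly_profile <- function(season_length = 62L, amplitude = 2, period = 7) {
  p <- amplitude * sin(2 * pi * seq_len(season_length) / period)
  p - mean(p)
}

#' Configuration for the synthetic seasonal-series generator
#'
#' Describes the study conditions the generator emulates: multi-year
#' blocks of daily values with a slow polynomial trend, a within-season
#' fluctuation pattern repeated identically across years, additive iid
#' Gaussian noise, and optional missing days. Defaults mirror a 15-year
#' July-August heat-index record: 62-day windows at a level near 29 degrees C
#' with a gentle quadratic drift, a weekly fluctuation of amplitude 2,
#' and noise sd 0.5.
#'
#' The trend polynomial is evaluated on the time axis affinely mapped to
#' `[-1, 1]` over the generated span (`trend_coeffs[1]` is the mid-series
#' level), so low-degree coefficients stay interpretable regardless of
#' the number of years. The seasonal profile is centred to mean zero so
#' the trend/season split is identifiable.
#'
#' @param years Number of seasonal windows to generate.
#' @param season_length Days per window (default 62).
#' @param trend_coeffs Polynomial coefficients, lowest order first.
#' @param seasonal_profile Vector of `season_length` phase effects.
#' @param noise_sd Gaussian noise standard deviation, `>= 0`.
#' @param missing_rate Independent row-drop probability in `[0, 1)`.
#' @param seed Integer RNG seed; the generator pins Mersenne-Twister with
#'   inversion normals so identical configs give identical output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(years = 15L, season_length = 62L,
                       trend_coeffs = c(29, 1.5, 0.8),
                       seasonal_profile = weekly_profile(season_length),
                       noise_sd = 0.5, missing_rate = 0, seed = 1L) {
  years <- as.integer(years)
  season_length <- as.integer(season_length)
  if (years < 0L) stop("'years' must be >= 0")
  if (season_length < 1L) stop("'season_length' must be >= 1")
  if (length(seasonal_profile) != season_length)
    stop("'seasonal_profile' must have length season_length")
  if (!is.numeric(noise_sd) || noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (missing_rate < 0 || missing_rate >= 1) stop("'missing_rate' must be in [0, 1)")
  structure(list(years = years, season_length = season_length,
                 trend_coeffs = trend_coeffs,
                 seasonal_profile = seasonal_profile - mean(seasonal_profile),
                 noise_sd = noise_sd, missing_rate = missing_rate,
                 seed = as.integer(seed),
                 rng = "Mersenne-Twister/Inversion"),
            class = "sim_config")
}

#' Generate a synthetic seasonal series with ground truth
#'
#' Draws `y0(t) = trend(t) + profile[phase(t)] + eps`, `eps ~ N(0, sd^2)`
#' iid, on progressive day ids concatenating the yearly windows, then
#' drops rows independently at the configured missing rate. The true
#' components are returned alongside the series so every pipeline stage
#' has an oracle.
#'
#' @param cfg A [sim_config()].
#' @return A list with `series` (a [season_series()] of the retained
#'   rows), `truth` (data frame `t`, `trend`, `seasonal`, `noise` for all
#'   generated slots, before dropping), and `config`.
#' @export
generate_series <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$years * cfg$season_length
  if (n == 0L)
    return(list(series = season_series(numeric(0), numeric(0), cfg$season_length),
                truth = data.frame(t = numeric(0), trend = numeric(0),
                                   seasonal = numeric(0), noise = numeric(0)),
                config = cfg))
  set.seed(cfg$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  t <- seq_len(n)
  u <- if (n > 1) (2 * t - (1 + n)) / (n - 1) else rep(0, n)
  trend <- rep(0, n)
  for (a in rev(cfg$trend_coeffs)) trend <- trend * u + a
  phase <- ((t - 1) %% cfg$season_length) + 1
  seasonal <- cfg$seasonal_profile[phase]
  noise <- stats::rnorm(n, 0, cfg$noise_sd)
  keep <- if (cfg$missing_rate > 0) stats::runif(n) >= cfg$missing_rate else rep(TRUE, n)
  y0 <- trend + seasonal + noise
  list(series = season_series(t[keep], y0[keep], cfg$season_length),
       truth = data.frame(t = t, trend = trend, seasonal = seasonal, noise = noise),
       config = cfg)
}

#' Generate synthetic daily weather rows
#'
#' Seeded daily maximum temperature (a within-season sinusoid around a
#' summer level, plus Gaussian noise, clipped to 15..45 degrees C) and
#' relative humidity (uniform 20..95%), for end-to-end exercise of the
#' heat-index transform.
#'
#' @param cfg A [sim_config()]; `years`, `season_length` and `seed` are
#'   used.
#' @return Data frame with columns `t`, `tmax_c`, `rh_pct`.
#' @export
generate_weather <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$years * cfg$season_length
  if (n == 0L)
    return(data.frame(t = numeric(0), tmax_c = numeric(0), rh_pct = numeric(0)))
  set.seed(cfg$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  t <- seq_len(n)
  phase <- ((t - 1) %% cfg$season_length) + 1
  tmax <- 29 + 4 * sin(pi * phase / cfg$season_length) + stats::rnorm(n, 0, 1.5)
  data.frame(t = t,
             tmax_c = pmin(pmax(tmax, 15), 45),
             rh_pct = stats::runif(n, 20, 95))
}
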
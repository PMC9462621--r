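#' STL-ARIMA pipeline forecast
#'
#' The headline forecaster: the series is STL-decomposed (period 12), the
#' trend component's stationarity is checked (augmented Dickey-Fuller,
#' recorded in the result), and the components are then modelled separately
#' before recomposition: the seasonal component is extended by repeating its
#' last full cycle (seasonal-naive), while the trend and remainder each get
#' an AIC-selected ARIMA model ([auto_arima_grid_search()]) and are
#' forecast by [forecast_arima()]. Point forecasts are the sum of the three
#' component forecasts; interval variances are summed across the two ARIMA
#' components under an independence assumption (the seasonal-naive extension
#' contributes no variance).
#'
#' Series shorter than 24 months cannot support the seasonal fit; the
#' function then falls back, with a warning, to a single auto-ARIMA model on
#' the raw series. The same fallback is used if the component models cannot
#' be fitted.
#'
#' @param series A [monthly_series()] (or numeric vector).
#' @param horizon Positive forecast horizon in months; horizons beyond 24
#'   (two seasonal cycles) draw a warning.
#' @param grid Order bounds for the component searches ([arima_grid()]).
#' @param level Interval level.
#' @param period Seasonal period (12 for monthly data).
#'
#' @return A `refcast_forecast` with attributes `components` (the component
#'   forecasts and decomposition) and `trend_stationary` (the ADF verdict,
#'   or `NA` if the test degenerated).
#' @export
stl_arima_forecast <- function(series, horizon = 12L, grid = arima_grid(),
                               level = 0.95, period = 12L) {
  horizon <- as.integer(horizon)
  if (is.na(horizon) || horizon < 1L) stop("`horizon` must be positive", call. = FALSE)
  if (horizon > 2L * period) {
    warning(sprintf("horizon %d extends beyond two seasonal cycles; treat the extrapolation with caution",
                    horizon), call. = FALSE)
  }
  months <- NULL
  if (inherits(series, "monthly_series")) {
    months <- month_seq(next_month(series$month[nrow(series)]), horizon)
    y <- series$count
  } else y <- as.numeric(series)

  raw_fallback <- function(why) {
    warning(sprintf("STL-ARIMA fallback to raw auto-ARIMA: %s", why), call. = FALSE)
    fit <- auto_arima_grid_search(y, grid = grid)
    fc <- forecast_arima(fit, y, horizon = horizon, level = level, months = months)
    fc$model <- "stl_arima(raw fallback)"
    fc
  }
  if (length(y) < 2L * period) {
    return(raw_fallback(sprintf("series has %d months, fewer than two seasonal cycles", length(y))))
  }

  dec <- stl_decompose(y, period = period)
  adf <- tryCatch(stationarity_test(dec$trend), error = function(e) NULL)

  cycle <- utils::tail(dec$seasonal, period)
  seasonal_fc <- cycle[((seq_len(horizon) - 1L) %% period) + 1L]

  component_fc <- tryCatch({
    trend_fit <- auto_arima_grid_search(dec$trend, grid = grid)
    rem_fit <- auto_arima_grid_search(dec$remainder, grid = grid)
    list(trend = forecast_arima(trend_fit, dec$trend, horizon = horizon, level = level),
         remainder = forecast_arima(rem_fit, dec$remainder, horizon = horizon, level = level),
         trend_fit = trend_fit, remainder_fit = rem_fit)
  }, error = function(e) NULL)
  if (is.null(component_fc)) {
    return(raw_fallback("component models could not be fitted"))
  }

  z <- stats::qnorm((1 + level) / 2)
  var_sum <- ((component_fc$trend$point - component_fc$trend$lower) / z)^2 +
    ((component_fc$remainder$point - component_fc$remainder$lower) / z)^2
  point <- component_fc$trend$point + component_fc$remainder$point + seasonal_fc
  half <- z * sqrt(var_sum)
  fc <- new_forecast(point, point - half, point + half, level,
                     months = months, model = "stl_arima")
  attr(fc, "components") <- list(decomposition = dec,
                                 seasonal = seasonal_fc,
                                 trend = component_fc$trend,
                                 remainder = component_fc$remainder,
                                 trend_order = component_fc$trend_fit$order,
                                 remainder_order = component_fc$remainder_fit$order)
  attr(fc, "trend_stationary") <- if (is.null(adf)) NA else adf$stationary
  fc
}
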
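#' Random-walk (naive) baseline forecast
#'
#' Every point forecast equals the last observed value; the step-h interval
#' half-width is `z(level) * sigma_hat * sqrt(h)` with `sigma_hat` the
#' standard deviation of the one-step differences of the training series.
#' A single-observation series has no difference to estimate from: the
#' intervals collapse to the point with a warning.
#'
#' @param series A [monthly_series()] or numeric vector.
#' @param horizon Positive forecast horizon.
#' @param level Interval level (point forecasts do not depend on it).
#' @return A `refcast_forecast`.
#' @export
random_walk_forecast <- function(series, horizon = 12L, level = 0.95) {
  parts <- comparator_input(series, horizon)
  y <- parts$y
  last <- y[length(y)]
  point <- rep(last, horizon)
  if (length(y) < 2L) {
    warning("single-observation series: random-walk interval width is undefined, returning point +/- 0",
            call. = FALSE)
    half <- rep(0, horizon)
  } else {
    s <- stats::sd(diff(y))
    half <- stats::qnorm((1 + level) / 2) * s * sqrt(seq_len(horizon))
  }
  new_forecast(point, point - half, point + half, level,
               months = parts$months, model = "random_walk")
}

#' Historical-average baseline forecast
#'
#' Every point forecast equals the arithmetic mean of the full training
#' series; the (constant) interval half-width is
#' `z(level) * sigma_hat * sqrt(1 + 1/n)`.
#'
#' @inheritParams random_walk_forecast
#' @return A `refcast_forecast`.
#' @export
historical_average_forecast <- function(series, horizon = 12L, level = 0.95) {
  parts <- comparator_input(series, horizon)
  y <- parts$y
  n <- length(y)
  point <- rep(mean(y), horizon)
  s <- if (n < 2L) 0 else stats::sd(y)
  half <- rep(stats::qnorm((1 + level) / 2) * s * sqrt(1 + 1 / n), horizon)
  new_forecast(point, point - half, point + half, level,
               months = parts$months, model = "historical_average")
}

comparator_input <- function(series, horizon) {
  horizon <- as.integer(horizon)
  if (is.na(horizon) || horizon < 1L) stop("`horizon` must be positive", call. = FALSE)
  months <- NULL
  if (inherits(series, "monthly_series")) {
    months <- month_seq(next_month(series$month[nrow(series)]), horizon)
    y <- series$count
  } else y <- as.numeric(series)
  if (length(y) == 0L) stop("empty series", call. = FALSE)
  list(y = y, months = months)
}

#' Configuration of the additive regression forecaster
#'
#' @param n_changepoints Number of candidate trend changepoints, evenly
#'   spaced over the first 80% of the training span.
#' @param changepoint_penalty Non-negative L1-style shrinkage weight on the
#'   changepoint slope changes (larger = straighter trend); approximated by
#'   iteratively reweighted least squares.
#' @param fourier_order Number of yearly Fourier harmonics (period 12).
#' @param custom_windows List of length-2 month vectors (start, end,
#'   inclusive); each window gets an indicator-level effect, e.g. a lockdown
#'   period.
#' @param level Interval level.
#' @return An `additive_model_config` list.
#' @export
additive_model_config <- function(n_changepoints = 10L, changepoint_penalty = 10,
                                  fourier_order = 3L, custom_windows = list(),
                                  level = 0.95) {
  if (changepoint_penalty < 0) stop("`changepoint_penalty` must be non-negative", call. = FALSE)
  fourier_order <- as.integer(fourier_order)
  if (fourier_order < 1L) stop("`fourier_order` must be positive", call. = FALSE)
  if (!is.list(custom_windows)) custom_windows <- list(custom_windows)
  structure(list(n_changepoints = as.integer(n_changepoints),
                 changepoint_penalty = changepoint_penalty,
                 fourier_order = fourier_order,
                 custom_windows = lapply(custom_windows, as_month),
                 level = level),
            class = "additive_model_config")
}

#' Additive regression forecast (piecewise trend + Fourier seasonality)
#'
#' A from-scratch additive regression in the spirit of decomposable
#' forecasting models: a piecewise-linear growth trend whose slope changes
#' at evenly spaced candidate changepoints are shrunk by an L1-style
#' penalty, a yearly Fourier seasonality block, and indicator effects over
#' user-declared custom windows (e.g. a lockdown period), fitted by
#' penalised least squares. Weekly seasonality is omitted: monthly data
#' cannot express it. Forecasts extrapolate the final trend segment and the
#' Fourier terms; window effects apply only to forecast months a declared
#' window covers. Intervals are Gaussian with constant half-width from the
#' residual standard deviation.
#'
#' @param series A [monthly_series()] (or numeric vector; custom windows
#'   then need month labels to land on and are ignored with a warning).
#' @param horizon Positive forecast horizon.
#' @param config An [additive_model_config()].
#' @return A `refcast_forecast` with a `coefficients` attribute (trend base
#'   slope, per-changepoint slope changes, Fourier and window coefficients).
#' @export
additive_regression_forecast <- function(series, horizon = 12L,
                                         config = additive_model_config()) {
  parts <- comparator_input(series, horizon)
  y <- parts$y
  n <- length(y)
  if (n < 24L) stop("the additive model needs at least 24 months of training data", call. = FALSE)
  all_months <- if (inherits(series, "monthly_series")) {
    c(series$month, parts$months)
  } else NULL
  if (is.null(all_months) && length(config$custom_windows)) {
    warning("custom windows ignored: the input has no month labels", call. = FALSE)
    config$custom_windows <- list()
  }

  t_all <- seq_len(n + horizon)
  K <- config$n_changepoints
  changepoints <- if (K > 0L) unique(pmax(2L, round(0.8 * n * seq_len(K) / (K + 1L)))) else integer(0)
  X_all <- cbind(intercept = 1, t = t_all)
  for (s in changepoints) X_all <- cbind(X_all, pmax(0, t_all - s))
  n_cp <- length(changepoints)
  for (k in seq_len(config$fourier_order)) {
    X_all <- cbind(X_all, cos(2 * pi * k * t_all / 12))
    sin_col <- sin(2 * pi * k * t_all / 12)
    if (max(abs(sin_col)) > 1e-8) X_all <- cbind(X_all, sin_col)
  }
  n_fourier <- ncol(X_all) - 2L - n_cp
  for (w in config$custom_windows) {
    X_all <- cbind(X_all, as.numeric(all_months >= w[1L] & all_months <= w[2L]))
  }
  n_win <- length(config$custom_windows)

  X <- X_all[seq_len(n), , drop = FALSE]
  cp_idx <- if (n_cp) 2L + seq_len(n_cp) else integer(0)
  beta <- penalised_lm(X, y, cp_idx, config$changepoint_penalty)
  if (is.null(beta)) stop("additive model fit failed: rank-deficient design", call. = FALSE)

  fitted <- drop(X %*% beta)
  resid <- y - fitted
  df <- max(n - ncol(X), 1L)
  sigma <- sqrt(sum(resid^2) / df)
  point <- drop(X_all[n + seq_len(horizon), , drop = FALSE] %*% beta)
  half <- rep(stats::qnorm((1 + config$level) / 2) * sigma, horizon)
  fc <- new_forecast(point, point - half, point + half, config$level,
                     months = parts$months, model = "additive_regression")
  attr(fc, "coefficients") <- list(
    intercept = beta[1L], base_slope = beta[2L],
    changepoint_deltas = if (n_cp) beta[cp_idx] else numeric(0),
    changepoints = changepoints,
    fourier = if (n_fourier) beta[2L + n_cp + seq_len(n_fourier)] else numeric(0),
    windows = if (n_win) beta[ncol(X) - n_win + seq_len(n_win)] else numeric(0),
    sigma = sigma)
  fc
}

# Least squares with an L1-style penalty on the columns in `pen_idx`,
# approximated by iteratively reweighted ridge steps.
penalised_lm <- function(X, y, pen_idx, lambda, n_iter = 25L, eps = 1e-8) {
  p <- ncol(X)
  pen_base <- rep(0, p)
  ridge <- diag(1e-10, p)  # numerical stabiliser
  beta <- NULL
  w <- rep(1, length(pen_idx))
  for (it in seq_len(max(1L, if (lambda > 0 && length(pen_idx)) n_iter else 1L))) {
    pen <- pen_base
    pen[pen_idx] <- lambda * w
    A <- crossprod(X) + diag(x = pen, nrow = p) + ridge
    beta_new <- tryCatch(solve(A, crossprod(X, y)), error = function(e) NULL)
    if (is.null(beta_new)) return(beta)
    if (!is.null(beta) && max(abs(beta_new - beta)) < 1e-10) { beta <- beta_new; break }
    beta <- beta_new
    if (length(pen_idx)) w <- 1 / (abs(beta[pen_idx]) + eps)
  }
  drop(beta)
}

#' Wrap a forecasting procedure as an evaluator-compatible adapter
#'
#' The adapter contract lets any forecaster — including external models such
#' as a neural network trained elsewhere — plug into [cross_validate()]:
#' `procedure(series, horizon, seed)` must return a forecast of exactly the
#' requested horizon, identically for identical inputs and seed. The horizon
#' is checked at every call; a mismatch is a contract-violation error.
#'
#' @param name Model name used in score tables.
#' @param procedure Function `(series, horizon, seed) -> refcast_forecast`
#'   (a list with a numeric `point` of the right length is accepted).
#' @return A `forecaster_adapter`.
#' @export
wrap_external_forecaster <- function(name, procedure) {
  stopifnot(is.character(name), length(name) == 1L, is.function(procedure))
  fit_and_forecast <- function(series, horizon, seed = 0L) {
    fc <- procedure(series, horizon, seed)
    if (is.null(fc$point) || length(fc$point) != horizon) {
      stop(sprintf("forecaster '%s' violated the adapter contract: returned %s points for horizon %d",
                   name, if (is.null(fc$point)) "no" else length(fc$point), horizon),
           call. = FALSE)
    }
    fc
  }
  structure(list(name = name, fit_and_forecast = fit_and_forecast),
            class = "forecaster_adapter")
}

#' Built-in forecaster adapters
#'
#' @param names Subset of `"stl_arima"`, `"random_walk"`,
#'   `"historical_average"`, `"additive"`.
#' @param grid,additive_config Settings forwarded to the respective models.
#' @param level Interval level used by all models.
#' @return Named list of `forecaster_adapter`s.
#' @export
builtin_forecasters <- function(names = c("stl_arima", "random_walk",
                                          "historical_average", "additive"),
                                grid = arima_grid(),
                                additive_config = additive_model_config(),
                                level = 0.95) {
  names <- match.arg(names, several.ok = TRUE)
  make <- list(
    stl_arima = function(series, horizon, seed) {
      suppressWarnings(stl_arima_forecast(series, horizon, grid = grid, level = level))
    },
    random_walk = function(series, horizon, seed) {
      random_walk_forecast(series, horizon, level = level)
    },
    historical_average = function(series, horizon, seed) {
      historical_average_forecast(series, horizon, level = level)
    },
    additive = function(series, horizon, seed) {
      additive_regression_forecast(series, horizon, config = additive_config)
    }
  )
  stats::setNames(lapply(names, function(nm) wrap_external_forecaster(nm, make[[nm]])),
                  names)
}
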
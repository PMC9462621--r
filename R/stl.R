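#' Seasonal-trend decomposition of a monthly series by loess (STL)
#'
#' Additive decomposition of a count series into seasonal, trend and
#' remainder components by the iterative STL procedure: the inner loop
#' alternates detrending, loess smoothing of each cycle-subseries (extended
#' one period at both ends), a low-pass filter (two length-`period` moving
#' averages, a length-3 moving average, then a loess of window
#' `low_pass_window`), deseasonalising, and a trend loess; an optional outer
#' loop downweights outlying remainders with bisquare weights. The remainder
#' is defined by subtraction, so `seasonal + trend + remainder` reproduces
#' the input exactly, by construction.
#'
#' Default smoother spans are the classic choices for this decomposition:
#' seasonal window 13 at degree 0 (near-periodic seasonality for monthly
#' data), trend window the smallest odd integer not less than
#' `1.5 * period / (1 - 1.5 / seasonal_window)`, low-pass window the smallest
#' odd integer not less than `period`, 2 inner and 0 outer iterations.
#'
#' @param series A [monthly_series()] or numeric vector.
#' @param period Seasonal period in observations (12 for monthly data).
#' @param seasonal_window,seasonal_degree Loess span (odd) and degree for the
#'   cycle-subseries smoother.
#' @param trend_window,trend_degree Loess span and degree for the trend
#'   smoother (`NULL` span = default above).
#' @param low_pass_window Loess span for the low-pass stage (`NULL` =
#'   default above).
#' @param inner_iterations,outer_iterations Inner-loop passes and robust
#'   outer-loop passes.
#'
#' @return An object of class `stl_decomposition`: list with numeric vectors
#'   `seasonal`, `trend`, `remainder` (each the input's length), the input
#'   `values`, `months` (or `NULL`), and `period`.
#' @export
stl_decompose <- function(series, period = 12L,
                          seasonal_window = 13L, seasonal_degree = 0L,
                          trend_window = NULL, trend_degree = 1L,
                          low_pass_window = NULL,
                          inner_iterations = 2L, outer_iterations = 0L) {
  months <- NULL
  if (inherits(series, "monthly_series")) {
    months <- series$month
    y <- series$count
  } else {
    y <- as.numeric(series)
  }
  n <- length(y)
  period <- as.integer(period)
  if (period < 2L) stop("`period` must be at least 2", call. = FALSE)
  if (n < 2L * period) {
    stop(sprintf("insufficient data: STL needs at least 2 full periods (%d points), got %d",
                 2L * period, n), call. = FALSE)
  }
  seasonal_window <- next_odd(seasonal_window)
  if (is.null(trend_window)) {
    trend_window <- next_odd(ceiling(1.5 * period / (1 - 1.5 / seasonal_window)))
  } else trend_window <- next_odd(trend_window)
  if (is.null(low_pass_window)) low_pass_window <- next_odd(period)
  else low_pass_window <- next_odd(low_pass_window)

  trend <- numeric(n)
  seasonal <- numeric(n)
  rw <- rep(1, n)
  for (outer in seq_len(max(1L, outer_iterations + 1L))) {
    for (inner in seq_len(inner_iterations)) {
      detrended <- y - trend
      # cycle-subseries smoothing, each extended one period at both ends
      C <- numeric(n + 2L * period)
      for (k in seq_len(period)) {
        idx <- seq(k, n, by = period)
        m <- length(idx)
        pos <- seq_len(m)
        sm <- loess_smooth(pos, detrended[idx], window = seasonal_window,
                           degree = seasonal_degree,
                           eval_points = c(0, pos, m + 1),
                           weights = rw[idx])
        C[k + (0:(m + 1L)) * period] <- sm
      }
      # low-pass: MA(period) twice, MA(3), then trend-degree loess
      L <- moving_average(moving_average(moving_average(C, period), period), 3L)
      L <- loess_smooth(seq_len(n), L, window = low_pass_window, degree = 1L)
      seasonal <- C[period + seq_len(n)] - L
      deseason <- y - seasonal
      trend <- loess_smooth(seq_len(n), deseason, window = trend_window,
                            degree = trend_degree, weights = rw)
    }
    if (outer <= outer_iterations) {
      r <- y - seasonal - trend
      s <- 6 * stats::median(abs(r))
      rw <- if (s > 0) bisquare(r / s) else rep(1, n)
    }
  }
  remainder <- y - seasonal - trend  # additivity is an identity
  structure(list(seasonal = seasonal, trend = trend, remainder = remainder,
                 values = y, months = months, period = period),
            class = "stl_decomposition")
}

#' @export
print.stl_decomposition <- function(x, ...) {
  cat(sprintf("<stl_decomposition> n = %d, period = %d\n", length(x$values), x$period))
  cat(sprintf("  component sd: seasonal %.3f, trend %.3f, remainder %.3f\n",
              stats::sd(x$seasonal), stats::sd(x$trend), stats::sd(x$remainder)))
  invisible(x)
}

#' Write decomposition components as CSV
#'
#' Four columns: month (YYYY-MM, or the 1-based index when the input was a
#' bare vector), seasonal, trend, remainder.
#'
#' @param decomposition An `stl_decomposition`.
#' @param path Output file path.
#' @export
write_decomposition_csv <- function(decomposition, path) {
  month <- if (!is.null(decomposition$months)) {
    format(decomposition$months, "%Y-%m")
  } else seq_along(decomposition$values)
  utils::write.csv(data.frame(month = month,
                              seasonal = decomposition$seasonal,
                              trend = decomposition$trend,
                              remainder = decomposition$remainder),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Centred moving average of span k; shrinks length by k - 1.
moving_average <- function(x, k) {
  n <- length(x) - k + 1L
  cs <- cumsum(c(0, x))
  (cs[(k + 1L):(length(x) + 1L)] - cs[seq_len(n)]) / k
}

next_odd <- function(k) {
  k <- as.integer(ceiling(k))
  if (k %% 2L == 0L) k + 1L else k
}
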
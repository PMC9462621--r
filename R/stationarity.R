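#' Augmented Dickey-Fuller stationarity check
#'
#' Tests the unit-root null against level stationarity with the augmented
#' Dickey-Fuller regression (constant, no linear trend):
#' \deqn{\Delta y_t = \alpha + \rho y_{t-1} + \sum_{i=1}^{L} \gamma_i
#'   \Delta y_{t-i} + e_t}
#' with the lag order set by Schwert's rule
#' `L = floor(12 * (n/100)^(1/4))` (capped so the regression keeps at least
#' 10 residual degrees of freedom). The t-ratio of `rho` is compared against
#' MacKinnon's finite-sample critical values for the constant-only case; the
#' reported p-value is a monotone interpolation over the tabulated 1%, 5%
#' and 10% levels, so values outside (0.01, 0.10) are bounds rather than
#' exact tail probabilities.
#'
#' @param values Numeric sequence (length >= 10, non-constant).
#' @param alpha Significance level for the stationarity call.
#'
#' @return List with `stationary` (logical: unit-root null rejected at
#'   `alpha`), `statistic` (the Dickey-Fuller t-ratio), `p_value_or_bound`,
#'   `lag` and `n`.
#' @export
stationarity_test <- function(values, alpha = 0.05) {
  y <- as.numeric(values)
  n <- length(y)
  if (n < 10L) stop("stationarity test needs at least 10 observations", call. = FALSE)
  if (max(y) - min(y) < .Machine$double.eps^0.5 * max(1, abs(y[1L]))) {
    stop("degenerate input: the sequence is constant, the test is undefined",
         call. = FALSE)
  }
  lag <- floor(12 * (n / 100)^0.25)
  lag <- max(0L, min(lag, n - 12L))  # keep >= 10 residual df
  dy <- diff(y)
  t_idx <- (lag + 1L):(n - 1L)       # rows of the ADF regression
  X <- cbind(intercept = 1, lag1 = y[t_idx])
  if (lag > 0L) {
    for (i in seq_len(lag)) X <- cbind(X, dy[t_idx - i])
  }
  yy <- dy[t_idx]
  fit <- stats::lm.fit(X, yy)
  res <- fit$residuals
  df <- length(yy) - ncol(X)
  s2 <- sum(res^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  se_rho <- sqrt(s2 * XtXinv[2L, 2L])
  stat <- fit$coefficients[2L] / se_rho
  cv <- adf_critical_values(length(yy))
  p <- adf_p_interp(stat, cv)
  list(stationary = unname(stat < stats::approx(c(0.01, 0.05, 0.10), cv,
                                                xout = alpha, rule = 2)$y),
       statistic = unname(stat), p_value_or_bound = p,
       lag = lag, n = length(yy))
}

# MacKinnon finite-sample response-surface critical values, constant-only
# case, at the 1% / 5% / 10% levels.
adf_critical_values <- function(T) {
  b <- rbind(c(-3.43035, -6.5393, -16.786, -79.433),
             c(-2.86154, -2.8903, -4.234, -40.040),
             c(-2.56677, -1.5384, -2.809, 0))
  b[, 1] + b[, 2] / T + b[, 3] / T^2 + b[, 4] / T^3
}

adf_p_interp <- function(stat, cv) {
  levels <- c(0.01, 0.05, 0.10)
  if (stat <= cv[1L]) return(0.01)   # bound: at most 1%
  if (stat >= cv[3L]) return(0.10)   # bound: at least 10%
  stats::approx(cv, levels, xout = stat)$y
}
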
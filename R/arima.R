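#' Difference a sequence
#'
#' @param values Numeric sequence.
#' @param d Non-negative differencing degree; the result is shorter by `d`.
#' @return The d-th order difference of `values`.
#' @export
difference <- function(values, d) {
  d <- as.integer(d)
  if (d < 0L) stop("`d` must be non-negative", call. = FALSE)
  if (d >= length(values)) {
    stop(sprintf("insufficient data: cannot difference %d values %d times",
                 length(values), d), call. = FALSE)
  }
  if (d == 0L) return(as.numeric(values))
  diff(as.numeric(values), differences = d)
}

#' ARIMA order
#'
#' @param p,d,q Non-negative integers: autoregressive lag order, degree of
#'   differencing, moving-average order.
#' @return Named integer vector of class `arima_order`.
#' @export
arima_order <- function(p, d, q) {
  ord <- as.integer(c(p = p, d = d, q = q))
  if (anyNA(ord) || any(ord < 0L)) {
    stop("`p`, `d`, `q` must be non-negative integers", call. = FALSE)
  }
  names(ord) <- c("p", "d", "q")
  structure(ord, class = "arima_order")
}

#' Fit an ARIMA(p,d,q) model by exact Gaussian maximum likelihood
#'
#' The series is differenced `d` times, then an ARMA(p,q) model with
#' intercept is fitted by maximising the exact Gaussian likelihood, computed
#' with a Kalman filter on Harvey's state-space form with the innovation
#' variance concentrated out. Stationarity and invertibility are enforced
#' throughout the optimisation by the partial-autocorrelation
#' parametrisation (coefficients mapped through `tanh`-transformed partial
#' autocorrelations); starting values come from a Hannan-Rissanen two-step
#' regression. With `d > 0` the retained intercept acts as a drift term.
#'
#' `aic = 2k - 2 log L` with `k = p + q + include_mean + 1` (the innovation
#' variance is counted; with the default intercept, `k = p + q + 2`).
#'
#' @param values Numeric sequence (a [monthly_series()] is accepted).
#' @param order An [arima_order()] or length-3 vector `c(p, d, q)`.
#' @param include_mean Estimate an intercept on the differenced scale
#'   (default `TRUE`).
#' @param optim_control Passed to [stats::optim()]; defaults to
#'   `reltol = 1e-8`, `maxit = 500`.
#'
#' @return An object of class `arima_fit`: order, `ar` and `ma` coefficient
#'   vectors, `intercept`, `sigma2`, `loglik`, `aic`, `n_obs` (length after
#'   differencing), `diagnostics` (near-unit-root flag), and the data the
#'   model was estimated on.
#' @export
fit_arima <- function(values, order, include_mean = TRUE,
                      optim_control = list(reltol = 1e-8, maxit = 500)) {
  if (inherits(values, "monthly_series")) values <- values$count
  y <- as.numeric(values)
  if (!inherits(order, "arima_order")) order <- arima_order(order[1L], order[2L], order[3L])
  p <- order[["p"]]; d <- order[["d"]]; q <- order[["q"]]
  if (d >= length(y)) fit_failure(order, "series shorter than the differencing degree")
  z <- difference(y, d)
  n <- length(z)
  if (n < p + q + 3L) {
    fit_failure(order, sprintf("insufficient data: %d observations after differencing for p+q = %d",
                               n, p + q))
  }
  if (n < max(3L * (p + q + 1L), 20L)) {
    warning(sprintf("small sample for ARIMA(%d,%d,%d): %d observations after differencing; estimates may be unstable",
                    p, d, q, n), call. = FALSE)
  }
  scale <- stats::sd(z)
  if (!is.finite(scale) || scale == 0) scale <- max(abs(z), 1)

  neg2ll <- function(par) {
    cf <- par_to_coef(par, p, q, include_mean)
    lk <- arma_profile_lik(z, cf$phi, cf$theta, cf$mu)
    if (!lk$ok) return(1e10)
    n * log(max(lk$ssq / n, 1e-20 * scale^2)) + lk$sumlog
  }

  start <- arma_start(z, p, q, include_mean)
  opt <- tryCatch(
    if (length(start)) {
      stats::optim(start, neg2ll, method = "BFGS", control = optim_control)
    } else {
      list(par = numeric(0), value = neg2ll(numeric(0)), convergence = 0L)
    },
    error = function(e) NULL
  )
  if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e10) {
    fit_failure(order, "likelihood optimisation failed")
  }
  if (!is.null(opt$convergence) && opt$convergence > 1L) {
    fit_failure(order, sprintf("optimiser did not converge (code %d)", opt$convergence))
  }
  cf <- par_to_coef(opt$par, p, q, include_mean)
  lk <- arma_profile_lik(z, cf$phi, cf$theta, cf$mu)
  sigma2 <- max(lk$ssq / n, 0)
  loglik <- -0.5 * (n * log(2 * pi) + n +
                      n * log(max(sigma2, 1e-20 * scale^2)) + lk$sumlog)
  k <- p + q + as.integer(include_mean) + 1L
  pacfs <- tanh(opt$par[seq_len(p + q)])
  structure(list(
    order = order, ar = cf$phi, ma = cf$theta, intercept = cf$mu,
    sigma2 = sigma2, loglik = loglik, aic = 2 * k - 2 * loglik,
    n_obs = n, k = k, include_mean = include_mean,
    diagnostics = list(near_unit_root = (p + q > 0L) && any(abs(pacfs) > 0.99),
                       optim_convergence = opt$convergence),
    history = y
  ), class = "arima_fit")
}

#' @export
print.arima_fit <- function(x, ...) {
  cat(sprintf("<arima_fit> ARIMA(%d,%d,%d)%s, n = %d\n",
              x$order[["p"]], x$order[["d"]], x$order[["q"]],
              if (x$include_mean) " with intercept" else "", x$n_obs))
  if (length(x$ar)) cat("  ar:", sprintf("%.4f", x$ar), "\n")
  if (length(x$ma)) cat("  ma:", sprintf("%.4f", x$ma), "\n")
  cat(sprintf("  intercept %.4f, sigma2 %.4f, loglik %.3f, aic %.3f\n",
              x$intercept, x$sigma2, x$loglik, x$aic))
  if (isTRUE(x$diagnostics$near_unit_root)) cat("  note: near-unit-root fit\n")
  invisible(x)
}

fit_failure <- function(order, reason) {
  cond <- structure(
    class = c("refcast_fit_failure", "error", "condition"),
    list(message = sprintf("ARIMA(%d,%d,%d) fit failed: %s",
                           order[["p"]], order[["d"]], order[["q"]], reason),
         call = NULL, order = order)
  )
  stop(cond)
}

# --- parametrisation -------------------------------------------------------

# Unconstrained parameter vector -> (phi, theta, mu). The first p entries
# are tanh-transformed partial autocorrelations of the AR polynomial, the
# next q the analogous quantities for the MA polynomial, optionally
# followed by the intercept.
par_to_coef <- function(par, p, q, include_mean) {
  phi <- if (p) pacf_to_ar(tanh(par[seq_len(p)])) else numeric(0)
  theta <- if (q) pacf_to_ar(tanh(par[p + seq_len(q)])) else numeric(0)
  mu <- if (include_mean) par[p + q + 1L] else 0
  list(phi = phi, theta = theta, mu = mu)
}

# Levinson-Durbin step: partial autocorrelations -> AR coefficients.
pacf_to_ar <- function(pa) {
  phi <- numeric(0)
  for (k in seq_along(pa)) {
    phi <- c(phi - pa[k] * rev(phi), pa[k])
  }
  phi
}

# Inverse recursion, used only to transform starting values; inputs are
# shrunk toward stationarity when needed.
ar_to_pacf <- function(phi) {
  k <- length(phi)
  pa <- numeric(k)
  while (k > 0L) {
    a <- phi[k]
    if (!is.finite(a) || abs(a) >= 1) a <- sign(a) * 0.95
    pa[k] <- a
    phi <- if (k > 1L) (phi[-k] + a * rev(phi[-k])) / (1 - a^2) else numeric(0)
    phi[!is.finite(phi)] <- 0
    k <- k - 1L
  }
  pmin(pmax(pa, -0.98), 0.98)
}

# Hannan-Rissanen starting values on the (differenced) series.
arma_start <- function(z, p, q, include_mean) {
  mu0 <- mean(z)
  if (p + q == 0L) return(if (include_mean) mu0 else numeric(0))
  zc <- z - mu0
  n <- length(zc)
  start_phi <- rep(0, p)
  start_theta <- rep(0, q)
  L <- min(max(8L, p + q + 5L), max(1L, n %/% 4L))
  e <- tryCatch({
    g <- stats::acf(zc, lag.max = L, type = "covariance", plot = FALSE,
                    demean = FALSE)$acf[, 1, 1]
    a <- levinson_ar(g, L)
    res <- numeric(n)
    for (t in seq_len(n)) {
      lags <- t - seq_len(min(L, t - 1L))
      res[t] <- zc[t] - sum(a[seq_along(lags)] * zc[lags])
    }
    res
  }, error = function(err) NULL)
  if (!is.null(e) && p + q > 0L) {
    m <- max(p, q)
    rows <- (m + 1L):n
    X <- NULL
    if (p) X <- cbind(X, sapply(seq_len(p), function(i) zc[rows - i]))
    if (q) X <- cbind(X, sapply(seq_len(q), function(i) e[rows - i]))
    beta <- tryCatch(stats::lm.fit(X, zc[rows])$coefficients,
                     error = function(err) NULL)
    if (!is.null(beta) && all(is.finite(beta))) {
      if (p) start_phi <- beta[seq_len(p)]
      if (q) start_theta <- beta[p + seq_len(q)]
    }
  }
  par <- c(atanh(ar_to_pacf(start_phi)), atanh(ar_to_pacf(start_theta)))
  if (include_mean) par <- c(par, mu0)
  par
}

# AR(L) coefficients from autocovariances g[1..L+1] (lag 0 first) by
# Levinson-Durbin.
levinson_ar <- function(g, L) {
  a <- numeric(0)
  v <- g[1L]
  for (k in seq_len(L)) {
    num <- g[k + 1L] - if (k > 1L) sum(a * g[k:2L]) else 0
    if (v <= 0) break
    refl <- num / v
    refl <- min(max(refl, -0.98), 0.98)
    a <- c(a - refl * rev(a), refl)
    v <- v * (1 - refl^2)
  }
  c(a, rep(0, L - length(a)))
}

# --- likelihood ------------------------------------------------------------

# Profile (sigma^2-concentrated) likelihood pieces of ARMA(p,q) with mean mu.
arma_profile_lik <- function(z, phi, theta, mu) {
  out <- arma_kalman(z - mu, phi, theta)
  out$ok <- isTRUE(out$ok) && is.finite(out$ssq) && is.finite(out$sumlog)
  out
}

# --- forecasting -----------------------------------------------------------

#' Forecast from a fitted ARIMA model
#'
#' Point forecasts propagate the Kalman one-step-ahead state of the fitted
#' ARMA model on the differenced scale (plus intercept), then integrate back
#' through the `d` differences. Interval half-widths are
#' `z(level) * sigma * sqrt(sum of squared psi weights)` where the psi
#' weights come from the full ARIMA operator `phi(B)(1-B)^d` with `theta(B)`,
#' so the uncertainty of the integration is included.
#'
#' @param fit An [fit_arima()] result.
#' @param history The series the fit was estimated on (defaults to the data
#'   stored in the fit).
#' @param horizon Positive forecast horizon.
#' @param level Interval level in (0, 1).
#' @param months Optional `Date` vector of forecast months for labelling.
#'
#' @return A `refcast_forecast`: list with `point`, `lower`, `upper`,
#'   `level`, `horizon`, `months`, `model`.
#' @export
forecast_arima <- function(fit, history = NULL, horizon = 12L, level = 0.95,
                           months = NULL) {
  horizon <- as.integer(horizon)
  if (is.na(horizon) || horizon < 1L) stop("`horizon` must be positive", call. = FALSE)
  if (is.null(history)) history <- fit$history
  if (inherits(history, "monthly_series")) history <- history$count
  y <- as.numeric(history)
  d <- fit$order[["d"]]; p <- fit$order[["p"]]; q <- fit$order[["q"]]
  z <- difference(y, d)
  lk <- arma_profile_lik(z, fit$ar, fit$ma, fit$intercept)
  if (!lk$ok) stop("cannot filter the supplied history with this fit", call. = FALSE)
  r <- max(p, q + 1L)
  Tm <- matrix(0, r, r)
  Tm[seq_len(p), 1L] <- fit$ar
  if (r > 1L) Tm[cbind(seq_len(r - 1L), 2L:r)] <- 1
  a <- lk$a_pred
  zhat <- numeric(horizon)
  for (h in seq_len(horizon)) {
    zhat[h] <- a[1L] + fit$intercept
    a <- drop(Tm %*% a)
  }
  point <- if (d == 0L) zhat else {
    full <- stats::diffinv(zhat, differences = d, xi = utils::tail(y, d))
    utils::tail(full, horizon)
  }
  psi <- arima_psi_weights(fit$ar, fit$ma, d, horizon)
  half <- stats::qnorm((1 + level) / 2) * sqrt(fit$sigma2 * cumsum(psi^2))
  new_forecast(point, point - half, point + half, level,
               months = months, model = sprintf("arima(%d,%d,%d)", p, d, q))
}

# psi (MA-infinity) weights of theta(B) / [phi(B)(1-B)^d], first `horizon`.
arima_psi_weights <- function(phi, theta, d, horizon) {
  phistar <- fold_differencing(phi, d)
  P <- length(phistar); Q <- length(theta)
  psi <- c(1, numeric(horizon - 1L))
  for (j in seq_len(horizon - 1L)) {
    val <- if (j <= Q) theta[j] else 0
    for (i in seq_len(min(j, P))) val <- val + phistar[i] * psi[j - i + 1L]
    psi[j + 1L] <- val
  }
  psi
}

# Coefficients of phi(B) * (1 - B)^d as an AR-type coefficient vector
# (signs such that the operator is 1 - sum(coef_i B^i)).
fold_differencing <- function(phi, d) {
  # operator coefficients including the leading 1
  op <- c(1, -phi)
  for (i in seq_len(d)) {
    op <- c(op, 0) - c(0, op)   # multiply by (1 - B)
  }
  -op[-1L]
}

new_forecast <- function(point, lower, upper, level, months = NULL, model = "") {
  stopifnot(length(lower) == length(point), length(upper) == length(point))
  structure(list(horizon = length(point), point = as.numeric(point),
                 lower = as.numeric(lower), upper = as.numeric(upper),
                 level = level, months = months, model = model),
            class = "refcast_forecast")
}

#' @export
print.refcast_forecast <- function(x, ...) {
  cat(sprintf("<forecast> %s, horizon %d, %g%% intervals\n",
              x$model, x$horizon, 100 * x$level))
  df <- data.frame(step = seq_len(x$horizon), point = round(x$point, 3),
                   lower = round(x$lower, 3), upper = round(x$upper, 3))
  if (!is.null(x$months)) df <- cbind(month = format(x$months, "%Y-%m"), df)
  print(utils::head(df, 12L), row.names = FALSE)
  invisible(x)
}

#' Write a forecast as CSV
#'
#' Columns: month (or step), point, lower, upper, level.
#' @param forecast A `refcast_forecast`.
#' @param path Output file path.
#' @export
write_forecast_csv <- function(forecast, path) {
  lead <- if (!is.null(forecast$months)) {
    data.frame(month = format(forecast$months, "%Y-%m"))
  } else data.frame(step = seq_len(forecast$horizon))
  utils::write.csv(cbind(lead, data.frame(point = forecast$point,
                                          lower = forecast$lower,
                                          upper = forecast$upper,
                                          level = forecast$level)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- automated order selection --------------------------------------------

#' Order-search grid bounds
#'
#' @param p_max,d_max,q_max Upper bounds of the (p, d, q) search grid.
#' @return A list of bounds for [auto_arima_grid_search()].
#' @export
arima_grid <- function(p_max = 3L, d_max = 2L, q_max = 3L) {
  list(p_max = as.integer(p_max), d_max = as.integer(d_max),
       q_max = as.integer(q_max))
}

#' Automated ARIMA order selection by AIC grid search
#'
#' Fits every order in the grid, skips orders whose fit fails (too little
#' data, non-convergence), and returns the fit with minimal AIC. Ties
#' (within 1e-6) are broken by fewest parameters, then lexicographically on
#' (p, d, q).
#'
#' @param values Numeric sequence or [monthly_series()].
#' @param grid An [arima_grid()].
#' @param include_mean Passed to [fit_arima()].
#' @return The winning `arima_fit`, with the number of attempted and failed
#'   orders recorded in `$search`.
#' @export
auto_arima_grid_search <- function(values, grid = arima_grid(),
                                   include_mean = TRUE) {
  orders <- expand.grid(p = 0:grid$p_max, d = 0:grid$d_max, q = 0:grid$q_max)
  orders <- orders[order(orders$p, orders$d, orders$q), , drop = FALSE]
  best <- NULL
  n_failed <- 0L
  for (i in seq_len(nrow(orders))) {
    fit <- tryCatch(
      suppressWarnings(fit_arima(values, arima_order(orders$p[i], orders$d[i], orders$q[i]),
                                 include_mean = include_mean)),
      refcast_fit_failure = function(e) NULL,
      error = function(e) NULL
    )
    if (is.null(fit)) { n_failed <- n_failed + 1L; next }
    if (is.null(best) || fit$aic < best$aic - 1e-6 ||
        (abs(fit$aic - best$aic) <= 1e-6 && fewer_params(fit, best))) {
      best <- fit
    }
  }
  if (is.null(best)) {
    stop(sprintf("no ARIMA model could be fitted: all %d orders in the grid failed",
                 nrow(orders)), call. = FALSE)
  }
  best$search <- list(n_orders = nrow(orders), n_failed = n_failed)
  best
}

fewer_params <- function(fit, best) {
  ka <- fit$order[["p"]] + fit$order[["q"]]
  kb <- best$order[["p"]] + best$order[["q"]]
  if (ka != kb) return(ka < kb)
  # lexicographic (p, d, q); the loop visits orders in that sequence,
  # so the incumbent already precedes later ties
  FALSE
}
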
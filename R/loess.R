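#' Locally weighted polynomial regression (loess) smoother
#'
#' The smoothing primitive the STL decomposition is built from: at each
#' evaluation point a polynomial of degree `degree` is fitted by weighted
#' least squares to the `window` nearest observations, with tricube
#' neighbourhood weights, and the fit is read off at the evaluation point.
#' Optional robustness iterations downweight large residuals with bisquare
#' weights, as in robust locally weighted regression.
#'
#' @param x Strictly increasing numeric predictor.
#' @param y Numeric response, same length as `x`.
#' @param window Odd positive integer: number of neighbouring points entering
#'   each local fit. A `window` larger than `length(x)` stretches the tricube
#'   bandwidth proportionally (all points always enter).
#' @param degree Local polynomial degree: 0, 1 or 2.
#' @param robustness_iterations Number of bisquare reweighting passes
#'   (0 = plain loess).
#' @param eval_points Points at which the smooth is evaluated
#'   (default: `x` itself).
#' @param weights Optional non-negative prior weights on the observations
#'   (used by the STL outer loop).
#'
#' @return Numeric vector of fitted values at `eval_points`.
#' @export
loess_smooth <- function(x, y, window, degree = 1L,
                         robustness_iterations = 0L,
                         eval_points = x, weights = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("`x` and `y` must have the same length", call. = FALSE)
  if (n == 0L) stop("empty input", call. = FALSE)
  if (any(diff(x) <= 0)) stop("`x` must be strictly increasing", call. = FALSE)
  degree <- as.integer(degree)
  if (!degree %in% 0:2) stop("`degree` must be 0, 1 or 2", call. = FALSE)
  window <- as.integer(window)
  if (window < degree + 2L) {
    stop("`window` must be at least degree + 2", call. = FALSE)
  }
  if (window %% 2L == 0L) window <- window + 1L
  if (is.null(weights)) weights <- rep(1, n)

  rw <- rep(1, n)
  iter <- 0L
  repeat {
    fit_at_x <- loess_pass(x, y, window, degree, x, weights * rw)
    if (iter >= robustness_iterations) break
    r <- y - fit_at_x
    s <- 6 * stats::median(abs(r))
    rw <- if (s > 0) bisquare(r / s) else rep(1, n)
    iter <- iter + 1L
  }
  if (identical(eval_points, x)) fit_at_x
  else loess_pass(x, y, window, degree, as.numeric(eval_points), weights * rw)
}

# One un-iterated loess pass with fixed total weights.
loess_pass <- function(x, y, window, degree, eval_points, w) {
  n <- length(x)
  q <- min(window, n)
  vapply(eval_points, function(e) {
    d <- abs(x - e)
    dq <- sort(d, partial = q)[q]
    if (window > n) dq <- dq * window / n  # stretched bandwidth beyond the data
    wt <- if (dq > 0) tricube(d / dq) else as.numeric(d == 0)
    wt <- wt * w
    keep <- wt > 0
    if (!any(keep)) {
      # every neighbour robustness-rejected: fall back to the plain
      # tricube weights so the fit stays defined
      wt <- if (dq > 0) tricube(d / dq) else as.numeric(d == 0)
      keep <- wt > 0
    }
    local_polyfit(x[keep] - e, y[keep], wt[keep], degree)
  }, numeric(1))
}

# Weighted polynomial fit in centred coordinates; returns the value at 0.
# Falls back to lower degree when the local design is rank deficient
# (e.g. all weight concentrated on fewer distinct x than degree + 1).
local_polyfit <- function(xc, yv, wt, degree) {
  for (deg in seq(degree, 0)) {
    if (length(unique(xc)) < deg + 1L) next
    X <- matrix(1, length(xc), 1L)
    if (deg > 0L) for (d in seq_len(deg)) X <- cbind(X, xc^d)
    XtW <- t(X * wt)
    A <- XtW %*% X
    b <- XtW %*% yv
    beta <- tryCatch(solve(A, b), error = function(e) NULL)
    if (!is.null(beta)) return(beta[1L])
  }
  sum(wt * yv) / sum(wt)
}

tricube <- function(u) {
  u <- pmin(abs(u), 1)
  (1 - u^3)^3
}

bisquare <- function(u) {
  u <- pmin(abs(u), 1)
  (1 - u^2)^2
}
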
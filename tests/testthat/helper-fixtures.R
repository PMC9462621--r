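# Shared fixtures and independent oracles used across the suite.

months_from <- function(start, n) seq(as.Date(start), by = "month", length.out = n)

# Deterministic trend + seasonal series as a monthly_series.
trend_seasonal_series <- function(n = 120, slope = 0.5, amp = 3, start = "2010-01-01") {
  t <- seq_len(n)
  y <- slope * t + amp * sin(2 * pi * t / 12)
  monthly_series(months_from(start, n), y - min(y))
}

# Brute-force weighted least-squares line via explicit normal equations.
wls_line_oracle <- function(x, y, w, x0) {
  sw <- sum(w); sx <- sum(w * x); sxx <- sum(w * x^2)
  sy <- sum(w * y); sxy <- sum(w * x * y)
  det <- sw * sxx - sx^2
  a <- (sxx * sy - sx * sxy) / det
  b <- (sw * sxy - sx * sy) / det
  a + b * x0
}

# Brute-force chi-square with explicit double loops.
chi_square_oracle <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- rs[i] * cs[j] / N
      stat <- stat + (tab[i, j] - e)^2 / e
    }
  }
  stat
}

# Table 2 grade (rows: intern, resident, attending) by period (columns:
# pre-pandemic year, lockdown year, post-lockdown months) counts.
grade_period_counts <- function() {
  matrix(c(23, 50, 8,
           30, 22, 10,
           31, 28, 6),
         nrow = 3,
         dimnames = list(c("intern", "resident", "attending"),
                         c("pre_covid", "covid", "post_covid")))
}

# Oracle grid search: stats::arima over the same order grid, minimal AIC.
# Fits whose AR or MA polynomial has a root essentially on the unit circle
# are excluded: those are the well-known boundary pile-up artifacts of the
# unconstrained optimiser, not better models.
oracle_grid_search <- function(z, p_max, d_max, q_max) {
  interior <- function(coefs, sign) {
    if (!length(coefs)) return(TRUE)
    all(Mod(polyroot(c(1, sign * coefs))) > 1.02)
  }
  best <- NULL
  best_aic <- Inf
  for (d in 0:d_max) for (p in 0:p_max) for (q in 0:q_max) {
    f <- tryCatch(suppressWarnings(stats::arima(z, c(p, d, q))),
                  error = function(e) NULL)
    if (is.null(f)) next
    co <- stats::coef(f)
    ar <- co[grep("^ar", names(co))]
    ma <- co[grep("^ma", names(co))]
    if (!interior(ar, -1) || !interior(ma, 1)) next
    if (stats::AIC(f) < best_aic - 1e-6) {
      best_aic <- stats::AIC(f)
      best <- c(p, d, q)
    }
  }
  list(order = best, aic = best_aic)
}
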
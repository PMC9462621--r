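#' Configuration for the monthly referral-series generator
#'
#' The generator draws monthly counts from a log-linear rate model:
#' \deqn{\log \mu_t = \beta_0 + \beta_1 t + \sum_k [a_k \cos(2\pi k t/12) +
#'   b_k \sin(2\pi k t/12)] + \delta \, 1\{t \in \mathrm{window}\}}
#' with Poisson or negative-binomial observation noise. The defaults emulate
#' the referral volumes of a growing specialist service observed over
#' 89 months (June 2014 to October 2021): a low starting rate rising to a
#' median monthly volume in the low teens, a mild yearly cycle, and a
#' candidate multiplicative level perturbation over the UK lockdown window
#' (March 2020 to February 2021).
#'
#' @param start_month First month of the series (`Date` or `"YYYY-MM"`).
#' @param n_months Number of months to generate (>= 1; downstream seasonal
#'   fitting needs >= 24).
#' @param baseline_log_rate Intercept on the log monthly rate.
#' @param trend_per_month Additive change of the log rate per month.
#' @param seasonal_amplitudes Matrix-like with columns
#'   `(harmonic, cos, sin)`; each row adds a Fourier harmonic of period 12 on
#'   the log rate. Use `NULL` for no seasonality.
#' @param shock_window `NULL`, or a length-2 month vector (start, end,
#'   inclusive) inside the series span over which `shock_log_effect` is added
#'   to the log rate.
#' @param shock_log_effect Additive log-rate effect inside `shock_window`;
#'   `log(0.9)` means a 10% rate reduction.
#' @param noise `"poisson"` or `"negative_binomial"`.
#' @param dispersion Negative-binomial size parameter (smaller = more
#'   over-dispersion); ignored for Poisson noise.
#' @param seed Integer seed; every draw is reproducible given it.
#'
#' @return A `series_generator_config` list.
#' @export
series_generator_config <- function(start_month = "2014-06",
                                    n_months = 89L,
                                    baseline_log_rate = log(3),
                                    trend_per_month = 0.018,
                                    seasonal_amplitudes = cbind(harmonic = 1, cos = 0.10, sin = 0.05),
                                    shock_window = c("2020-03", "2021-02"),
                                    shock_log_effect = log(0.9),
                                    noise = c("poisson", "negative_binomial"),
                                    dispersion = 10,
                                    seed = 1L) {
  noise <- match.arg(noise)
  n_months <- as.integer(n_months)
  if (is.na(n_months) || n_months < 1L) {
    stop("`n_months` must be a positive integer", call. = FALSE)
  }
  if (!is.null(seasonal_amplitudes)) {
    seasonal_amplitudes <- as.matrix(seasonal_amplitudes)
    if (ncol(seasonal_amplitudes) != 3L) {
      stop("`seasonal_amplitudes` needs columns (harmonic, cos, sin)", call. = FALSE)
    }
  }
  if (noise == "negative_binomial" && (!is.numeric(dispersion) || dispersion <= 0)) {
    stop("`dispersion` must be a positive real for negative-binomial noise", call. = FALSE)
  }
  start_month <- as_month(start_month)
  if (!is.null(shock_window)) {
    shock_window <- as_month(shock_window)
    if (length(shock_window) != 2L || shock_window[2L] < shock_window[1L]) {
      stop("`shock_window` must be (start, end) with start <= end", call. = FALSE)
    }
    last <- month_seq(start_month, n_months)[n_months]
    if (shock_window[1L] < start_month || shock_window[2L] > last) {
      stop("`shock_window` must lie inside the series span", call. = FALSE)
    }
  }
  structure(list(
    start_month = start_month, n_months = n_months,
    baseline_log_rate = baseline_log_rate, trend_per_month = trend_per_month,
    seasonal_amplitudes = seasonal_amplitudes,
    shock_window = shock_window, shock_log_effect = shock_log_effect,
    noise = noise, dispersion = dispersion, seed = as.integer(seed)
  ), class = "series_generator_config")
}

# Expected count per month implied by a generator config (the analytic mean).
expected_monthly_rate <- function(config) {
  t <- seq_len(config$n_months) - 1L
  log_rate <- config$baseline_log_rate + config$trend_per_month * t
  if (!is.null(config$seasonal_amplitudes)) {
    for (i in seq_len(nrow(config$seasonal_amplitudes))) {
      k <- config$seasonal_amplitudes[i, 1L]
      log_rate <- log_rate +
        config$seasonal_amplitudes[i, 2L] * cos(2 * pi * k * t / 12) +
        config$seasonal_amplitudes[i, 3L] * sin(2 * pi * k * t / 12)
    }
  }
  if (!is.null(config$shock_window)) {
    months <- month_seq(config$start_month, config$n_months)
    inside <- months >= config$shock_window[1L] & months <= config$shock_window[2L]
    log_rate[inside] <- log_rate[inside] + config$shock_log_effect
  }
  exp(log_rate)
}

#' Generate a synthetic monthly referral series
#'
#' @param config A [series_generator_config()].
#' @return A [monthly_series()] of length `config$n_months`; identical for a
#'   fixed config and seed.
#' @export
generate_monthly_series <- function(config) {
  if (!inherits(config, "series_generator_config")) {
    config <- do.call(series_generator_config, as.list(config))
  }
  mu <- expected_monthly_rate(config)
  counts <- with_local_seed(config$seed, {
    if (config$noise == "poisson") {
      stats::rpois(config$n_months, mu)
    } else {
      stats::rnbinom(config$n_months, size = config$dispersion, mu = mu)
    }
  })
  monthly_series(month_seq(config$start_month, config$n_months), counts)
}

#' Per-period attribute profile for the referral-record generator
#'
#' Defaults resemble the marginals of a pituitary referral cohort: grades
#' dominated by residents pre-pandemic with a shift toward interns and
#' attendings later, a roughly 70:30 urgent:emergency split, Glasgow Coma
#' Scores concentrated at 15, and right-skewed symptom durations with a
#' median of a few days to a week.
#'
#' @param start,end Period window (months, inclusive).
#' @param n Expected number of records in the period.
#' @param grade_probs Named probabilities over
#'   `c(intern, resident, attending, other)`.
#' @param urgency_probs Named probabilities over `c(urgent, emergency)`.
#' @param gcs_probs Probabilities over GCS values 3..15 (length 13).
#' @param symptom_meanlog,symptom_sdlog Log-normal parameters of symptom
#'   duration in days (rounded up to an integer >= 1).
#' @param specialty_probs,site_probs Named categorical distributions for the
#'   referring specialty and site. `site_probs = NULL` draws from 48 sites
#'   with geometrically decaying weights (a few high-volume local centres).
#'
#' @return A `period_profile` list.
#' @export
period_profile <- function(start, end, n,
                           grade_probs = c(intern = 0.27, resident = 0.58,
                                           attending = 0.10, other = 0.05),
                           urgency_probs = c(urgent = 0.70, emergency = 0.30),
                           gcs_probs = c(0.002, 0.002, 0.002, 0.002, 0.002, 0.004,
                                         0.004, 0.006, 0.008, 0.012, 0.02, 0.08, 0.856),
                           symptom_meanlog = log(6.5), symptom_sdlog = 1.4,
                           specialty_probs = c(emergency_medicine = 0.40,
                                               endocrinology = 0.27,
                                               neurology = 0.13, medicine = 0.12,
                                               ophthalmology = 0.04, other = 0.04),
                           site_probs = NULL) {
  if (is.null(site_probs)) {
    w <- 0.85^(0:47)
    site_probs <- stats::setNames(w / sum(w), sprintf("S%02d", 1:48))
  }
  for (p in list(grade_probs, urgency_probs, gcs_probs, specialty_probs, site_probs)) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-6) {
      stop("profile probabilities must be non-negative and sum to 1", call. = FALSE)
    }
  }
  if (length(gcs_probs) != 13L) {
    stop("`gcs_probs` must have length 13 (GCS 3..15)", call. = FALSE)
  }
  structure(list(start = as_month(start), end = as_month(end), n = as.integer(n),
                 grade_probs = grade_probs, urgency_probs = urgency_probs,
                 gcs_probs = gcs_probs, symptom_meanlog = symptom_meanlog,
                 symptom_sdlog = symptom_sdlog, specialty_probs = specialty_probs,
                 site_probs = site_probs),
            class = "period_profile")
}

#' Generate synthetic referral records
#'
#' Draws one row per referral with date uniform inside its period window and
#' categorical attributes from the period's profile. With `n` supplied, the
#' per-period counts are allocated proportionally to the profiles' `n`.
#'
#' @param n Total number of records, or `NULL` to use each profile's `n`.
#' @param period_profiles List of [period_profile()]s.
#' @param seed Integer seed.
#'
#' @return A data frame with columns `referral_date` (`Date`), `grade`,
#'   `specialty`, `urgency`, `gcs`, `symptom_duration_days`, `site_id`,
#'   ordered by referral date.
#' @export
generate_referral_records <- function(n = NULL, period_profiles, seed = 1L) {
  if (inherits(period_profiles, "period_profile")) {
    period_profiles <- list(period_profiles)
  }
  ns <- vapply(period_profiles, function(p) p$n, integer(1))
  if (!is.null(n)) {
    n <- as.integer(n)
    if (is.na(n) || n < 1L) stop("`n` must be a positive integer", call. = FALSE)
    alloc <- floor(n * ns / sum(ns))
    rem <- n - sum(alloc)
    if (rem > 0) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1L
    ns <- alloc
  }
  with_local_seed(seed, {
    pieces <- Map(function(p, np) {
      if (np == 0L) return(NULL)
      days <- seq(p$start, next_month(p$end) - 1, by = "day")
      data.frame(
        referral_date = sample(days, np, replace = TRUE),
        grade = sample(names(p$grade_probs), np, replace = TRUE, prob = p$grade_probs),
        specialty = sample(names(p$specialty_probs), np, replace = TRUE,
                           prob = p$specialty_probs),
        urgency = sample(names(p$urgency_probs), np, replace = TRUE,
                         prob = p$urgency_probs),
        gcs = sample(3:15, np, replace = TRUE, prob = p$gcs_probs),
        symptom_duration_days = pmax(1L, as.integer(ceiling(
          stats::rlnorm(np, p$symptom_meanlog, p$symptom_sdlog)))),
        site_id = sample(names(p$site_probs), np, replace = TRUE, prob = p$site_probs),
        stringsAsFactors = FALSE
      )
    }, period_profiles, as.list(ns))
    out <- do.call(rbind, pieces)
    out <- out[order(out$referral_date), , drop = FALSE]
    rownames(out) <- NULL
    validate_referral_records(out)
  })
}

# First day of the month after `m`.
next_month <- function(m) {
  seq(as_month(m), by = "month", length.out = 2L)[2L]
}

# Field-invariant checks shared by the generator and the CSV reader.
validate_referral_records <- function(records, source = "records") {
  required <- c("referral_date", "grade", "specialty", "urgency", "gcs",
                "symptom_duration_days", "site_id")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing required column(s): %s", source,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  bad_row <- function(ok, what) {
    if (!all(ok)) {
      stop(sprintf("%s: %s in row(s) %s", source, what,
                   paste(utils::head(which(!ok), 5L), collapse = ", ")),
           call. = FALSE)
    }
  }
  records$referral_date <- if (is.character(records$referral_date)) {
    as.Date(records$referral_date, format = "%Y-%m-%d")
  } else as.Date(records$referral_date)
  bad_row(!is.na(records$referral_date), "unparseable referral_date")
  bad_row(records$gcs >= 3 & records$gcs <= 15, "gcs outside [3, 15]")
  bad_row(records$symptom_duration_days >= 1, "symptom_duration_days < 1")
  bad_row(records$urgency %in% c("urgent", "emergency"), "urgency not urgent/emergency")
  records
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
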
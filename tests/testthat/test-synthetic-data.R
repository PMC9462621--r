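test_that("the series generator is reproducible and rejects invalid configs", {
  cfg <- series_generator_config(seed = 7)
  s1 <- generate_monthly_series(cfg)
  s2 <- generate_monthly_series(cfg)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 89L)
  expect_true(all(s1$count >= 0))
  s3 <- generate_monthly_series(series_generator_config(seed = 8))
  expect_false(identical(s1$count, s3$count))

  expect_error(series_generator_config(n_months = 0), "positive")
  expect_error(series_generator_config(n_months = 24, shock_window = c("2020-03", "2021-02")),
               "inside the series span")
  expect_error(series_generator_config(noise = "negative_binomial", dispersion = -1),
               "positive real")
})

test_that("generated counts recover the configured analytic rates", {
  # flat Poisson: sample mean within 3 standard errors of the true rate
  cfg <- series_generator_config(start_month = "2000-01", n_months = 1200,
                                 baseline_log_rate = log(10), trend_per_month = 0,
                                 seasonal_amplitudes = NULL, shock_window = NULL,
                                 seed = 21)
  s <- generate_monthly_series(cfg)
  se <- sqrt(10 / 1200)
  expect_lt(abs(mean(s$count) - 10), 3 * se)

  # a log(0.5) shock halves the rate inside the window
  cfg2 <- series_generator_config(start_month = "2000-01", n_months = 48,
                                  baseline_log_rate = log(400), trend_per_month = 0,
                                  seasonal_amplitudes = NULL,
                                  shock_window = c("2001-01", "2001-12"),
                                  shock_log_effect = log(0.5), seed = 22)
  s2 <- generate_monthly_series(cfg2)
  inside <- s2$month >= as.Date("2001-01-01") & s2$month <= as.Date("2001-12-01")
  ratio <- mean(s2$count[inside]) / mean(s2$count[!inside])
  expect_lt(abs(ratio - 0.5), 0.05)

  # negative-binomial noise over-disperses relative to Poisson
  cfg3 <- series_generator_config(start_month = "2000-01", n_months = 600,
                                  baseline_log_rate = log(20), trend_per_month = 0,
                                  seasonal_amplitudes = NULL, shock_window = NULL,
                                  noise = "negative_binomial", dispersion = 2, seed = 23)
  s3 <- generate_monthly_series(cfg3)
  expect_gt(stats::var(s3$count), 1.5 * mean(s3$count))
})

test_that("referral records follow the period profiles", {
  prof <- period_profile("2019-03", "2020-02", n = 10000,
                         grade_probs = c(intern = 0.4, resident = 0.48,
                                         attending = 0.12, other = 0),
                         urgency_probs = c(urgent = 1, emergency = 0))
  rec <- generate_referral_records(period_profiles = prof, seed = 31)
  expect_equal(nrow(rec), 10000L)
  expect_true(all(rec$urgency == "urgent"))
  expect_true(all(rec$gcs >= 3 & rec$gcs <= 15))
  expect_true(all(rec$symptom_duration_days >= 1))
  expect_true(all(rec$referral_date >= as.Date("2019-03-01") &
                    rec$referral_date <= as.Date("2020-02-29")))
  probs <- c(intern = 0.4, resident = 0.48, attending = 0.12)
  for (nm in names(probs)) {
    p <- probs[[nm]]
    expect_lt(abs(mean(rec$grade == nm) - p), 3 * sqrt(p * (1 - p) / 10000))
  }

  expect_error(period_profile("2019-03", "2020-02", n = 10,
                              urgency_probs = c(urgent = 0.7, emergency = 0.7)),
               "sum to 1")
})

test_that("record generation writes byte-identical CSV under a fixed seed", {
  prof <- period_profile("2020-01", "2020-12", n = 50)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_referrals_csv(generate_referral_records(period_profiles = prof, seed = 5), f1)
  write_referrals_csv(generate_referral_records(period_profiles = prof, seed = 5), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("aggregation to a monthly series counts and conserves records", {
  rec <- data.frame(
    referral_date = as.Date(c("2020-05-03", "2020-05-17", "2020-05-30")),
    grade = "intern", specialty = "endocrinology", urgency = "urgent",
    gcs = 15L, symptom_duration_days = 2L, site_id = "S01")
  s <- aggregate_records_to_series(rec, span = c("2020-04", "2020-06"))
  expect_equal(s$count, c(0, 3, 0))

  empty <- rec[0, ]
  s0 <- aggregate_records_to_series(empty, span = c("2020-01", "2020-04"))
  expect_equal(s0$count, rep(0, 4))

  prof <- period_profile("2018-01", "2019-12", n = 1000)
  rec2 <- generate_referral_records(period_profiles = prof, seed = 9)
  s2 <- aggregate_records_to_series(rec2, span = c("2018-01", "2019-12"))
  expect_equal(sum(s2$count), 1000)

  expect_error(aggregate_records_to_series(rec, span = c("2020-06", "2020-04")),
               "empty span")
  expect_error(aggregate_records_to_series(rec, span = c("2020-06", "2020-07")),
               "outside the requested span")
  trunc <- aggregate_records_to_series(rec, span = c("2020-06", "2020-07"),
                                       truncate = TRUE)
  expect_equal(trunc$count, c(0, 0))
})

test_that("the monthly series type enforces gap-free non-negative counts", {
  m <- months_from("2020-01-01", 3)
  expect_error(monthly_series(m, c(1, -2, 3)), "non-negative")
  expect_error(monthly_series(m[c(1, 3)], c(1, 2)), "gap-free")
  expect_error(monthly_series(m, c(1, 2)), "same length")
})
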
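test_that("the grade-by-period tables reproduce the published chi-square statistics", {
  tab <- grade_period_counts()
  full <- pearson_chi_square(tab)
  expect_equal(full$statistic, 11.9, tolerance = 0.05 / 11.9)
  expect_equal(full$df, 4L)
  expect_lt(full$p_value, 0.05)

  pre_during <- pearson_chi_square(tab[, c("pre_covid", "covid")])
  expect_equal(pre_during$statistic, 9.7, tolerance = 0.05 / 9.7)
  expect_equal(pre_during$df, 2L)

  pre_post <- pearson_chi_square(tab[, c("pre_covid", "post_covid")])
  expect_equal(pre_post$statistic, 6.0, tolerance = 0.05 / 6.0)
})

test_that("chi-square matches brute force and the established implementation", {
  m <- matrix(c(10, 20, 5, 10), 2)   # identical column proportions
  expect_equal(pearson_chi_square(m)$statistic, 0)
  expect_error(pearson_chi_square(matrix(c(0, 0, 3, 4), 2)), "degenerate table")
  expect_error(pearson_chi_square(matrix(1:3, 3, 1)), "at least 2")

  set.seed(41)
  for (i in 1:100) {
    tab <- matrix(rpois(6, 20) + 1, 2, 3)
    mine <- pearson_chi_square(tab)
    expect_equal(mine$statistic, chi_square_oracle(tab), tolerance = 1e-10)
    ref <- stats::chisq.test(tab, correct = FALSE)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Kruskal-Wallis matches closed-form rank sums and the oracle", {
  h <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(h$statistic, 7.2, tolerance = 1e-12)
  expect_equal(h$df, 2L)

  expect_equal(kruskal_wallis(list(c(2, 2, 2), c(2, 2)))$statistic, 0)

  set.seed(43)
  for (i in 1:50) {
    g <- list(rpois(8, 5), rpois(12, 6), rpois(10, 5))  # ties guaranteed
    mine <- kruskal_wallis(g)
    ref <- stats::kruskal.test(g)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }

  # invariance under strictly monotone transforms
  g <- list(rnorm(10), rnorm(12, 1), rnorm(8, 2))
  expect_equal(kruskal_wallis(g)$statistic,
               kruskal_wallis(lapply(g, function(v) exp(3 * v)))$statistic,
               tolerance = 1e-12)
})

test_that("Dunn post-hoc z statistics order by separation and align with H", {
  set.seed(47)
  g <- list(a = rnorm(20), b = rnorm(20, 0.3), c = rnorm(20, 5))
  d <- dunn_posthoc(g)
  sep <- d$z[d$group_i == "a" & d$group_j == "c"]
  expect_equal(max(abs(d$z)), max(abs(sep), abs(d$z[d$group_i == "b" | d$group_j == "b"])))
  expect_true(abs(sep) >= max(abs(d$z)) - 1e-12)

  # for two tie-free groups the pairwise z statistic squared equals the
  # Kruskal-Wallis H: check the identity by brute force on the pair
  pair <- list(x = rnorm(15), y = rnorm(12, 1))
  r12 <- rank(unlist(pair))
  rbar <- tapply(r12, rep(1:2, c(15, 12)), mean)
  N <- 27
  z_pair <- (rbar[1] - rbar[2]) / sqrt((N * (N + 1) / 12) * (1 / 15 + 1 / 12))
  expect_equal(unname(z_pair^2), kruskal_wallis(pair)$statistic, tolerance = 1e-10)
  expect_error(dunn_posthoc(pair), "at least 3")

  # family-wise behaviour under the null with BH correction
  set.seed(48)
  clean <- replicate(200, {
    gg <- list(rnorm(15), rnorm(15), rnorm(15))
    all(dunn_posthoc(gg)$p_adjusted >= 0.05)
  })
  expect_gte(mean(clean), 0.95)
})

test_that("Benjamini-Hochberg applies the step-up rule and is monotone in q", {
  r <- benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(r$rejected))

  r1 <- benjamini_hochberg(rep(1, 5), q = 0.05)
  expect_false(any(r1$rejected))
  expect_equal(r1$adjusted, rep(1, 5))

  r2 <- benjamini_hochberg(0.04, q = 0.05)
  expect_true(r2$rejected)
  expect_equal(r2$adjusted, 0.04)

  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")

  # adjusted values equal the established step-up adjustment
  set.seed(51)
  for (i in 1:20) {
    p <- runif(10)^2
    expect_equal(benjamini_hochberg(p)$adjusted, stats::p.adjust(p, "BH"),
                 tolerance = 1e-12)
    rej <- sapply(c(0.01, 0.05, 0.1, 0.2), function(q) benjamini_hochberg(p, q)$rejected)
    # raising q never un-rejects
    expect_true(all(rej[, -1][rej[, -ncol(rej)]]))
  }
})

test_that("KS and Bartlett checks match oracles and behave under the null", {
  set.seed(53)
  x <- rnorm(200, 3, 2)
  mine <- ks_normality(x)
  ref <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)

  ok <- replicate(100, ks_normality(rnorm(1000))$p_value > 0.05)
  expect_gte(mean(ok), 0.9)

  for (i in 1:20) {
    g <- list(rnorm(12, sd = 1), rnorm(15, sd = 1.5), rnorm(10, sd = 0.7))
    mb <- bartlett_test(g)
    rb <- stats::bartlett.test(g)
    expect_equal(mb$statistic, unname(rb$statistic), tolerance = 1e-10)
    expect_equal(mb$p_value, rb$p.value, tolerance = 1e-10)
  }
  expect_error(bartlett_test(list(rep(1, 5), rnorm(5))), "zero variance")
})

test_that("omnibus tests hold their nominal size under simulated nulls", {
  set.seed(57)
  kw_rej <- replicate(2000, {
    kruskal_wallis(list(rnorm(12), rnorm(12), rnorm(12)))$p_value < 0.05
  })
  expect_gte(mean(kw_rej), 0.03); expect_lte(mean(kw_rej), 0.07)

  chi_rej <- replicate(2000, {
    tab <- matrix(stats::rmultinom(1, 400, rep(1 / 6, 6)), 2, 3)
    pearson_chi_square(tab)$p_value < 0.05
  })
  expect_gte(mean(chi_rej), 0.03); expect_lte(mean(chi_rej), 0.07)
})

test_that("period summaries reproduce constructed data and feed the tests", {
  periods <- period_definitions()
  profiles <- list(
    period_profile("2019-03", "2020-02", n = 240, symptom_meanlog = log(3)),
    period_profile("2020-03", "2021-02", n = 240, symptom_meanlog = log(7)),
    period_profile("2021-03", "2021-09", n = 140, symptom_meanlog = log(9)))
  rec <- generate_referral_records(period_profiles = profiles, seed = 61)
  series <- aggregate_records_to_series(rec, span = c("2019-03", "2021-09"))
  out <- period_summary(rec, series, periods)

  expect_equal(out$summary$period, periods$name)
  expect_equal(out$summary$n_records, c(240L, 240L, 140L, 0L))
  expect_true(is.na(out$summary$monthly_volume[4]))  # forecast period: no data
  expect_true(is.na(out$summary$urgent_pct[4]))

  # the grade table fed to the chi-square equals the direct computation
  direct <- pearson_chi_square(out$grade_table)
  expect_equal(out$tests$grade$overall$statistic, direct$statistic)
  expect_equal(nrow(out$tests$grade$pairwise), 3L)
  expect_true(all(c("kruskal_wallis", "dunn") %in% names(out$tests$monthly_volume)))

  # constructed medians: all records in one month with known duration
  rec_fixed <- data.frame(
    referral_date = rep(as.Date("2019-06-15"), 5),
    grade = c("intern", "resident", "resident", "attending", "other"),
    specialty = "endocrinology", urgency = c("urgent", "urgent", "urgent", "emergency", "urgent"),
    gcs = 15L, symptom_duration_days = c(1L, 2L, 3L, 4L, 5L), site_id = "S01")
  s_fixed <- aggregate_records_to_series(rec_fixed, span = c("2019-03", "2020-02"))
  out2 <- period_summary(rec_fixed, s_fixed, periods)
  expect_equal(out2$summary$symptom_duration[1], "3 (2-4)")
  expect_equal(out2$summary$urgent_pct[1], 80)
  expect_equal(out2$summary$n_records[-1], c(0L, 0L, 0L))
})
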
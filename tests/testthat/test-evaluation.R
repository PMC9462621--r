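test_that("blocked folds respect geometry, determinism and the exact-minimum layout", {
  plan <- cv_plan(seed = 5)
  f1 <- make_blocked_folds(89, plan, repetition_seed = 42)
  expect_length(f1, 5)
  for (fold in f1) {
    expect_length(fold$train, 15)
    expect_length(fold$test, 12)
    expect_equal(max(fold$train) + 1L, min(fold$test))
  }
  tests <- unlist(lapply(f1, `[[`, "test"))
  expect_equal(anyDuplicated(tests), 0L)
  expect_identical(f1, make_blocked_folds(89, plan, repetition_seed = 42))
  expect_false(identical(f1, make_blocked_folds(89, plan, repetition_seed = 43)))

  # at the exact minimum length the layout is unique whatever the seed
  f_min1 <- make_blocked_folds(75, plan, repetition_seed = 1)
  f_min2 <- make_blocked_folds(75, plan, repetition_seed = 999)
  expect_identical(f_min1, f_min2)
  expect_error(make_blocked_folds(74, plan), "minimum is")
})

test_that("no training index ever reaches into a fold's test block", {
  plan <- cv_plan(seed = 7)
  violations <- 0L
  for (r in 1:100) {
    for (fold in make_blocked_folds(89, plan, repetition_seed = r)) {
      if (max(fold$train) >= min(fold$test)) violations <- violations + 1L
    }
  }
  expect_equal(violations, 0L)
})

test_that("median error metrics match hand-computed values", {
  expect_equal(median_absolute_error(c(10, 12), c(11, 15)), 2.0)
  expect_equal(median_absolute_error(1:5, 1:5), 0)
  # one gross outlier among nine exact predictions leaves the median at zero
  a <- rep(10, 10); p <- a; p[1] <- 1000
  expect_equal(median_absolute_error(a, p), 0)
  expect_error(median_absolute_error(1:3, 1:4), "same length")

  expect_equal(median_absolute_percentage_error(c(10, 20), c(11, 15)), 17.5)
  expect_equal(median_absolute_percentage_error(c(3, 7), c(3, 7)), 0)
  expect_warning(v <- median_absolute_percentage_error(c(0, 10), c(5, 10)),
                 "zero-actual")
  expect_equal(v, 0)
  expect_error(median_absolute_percentage_error(c(0, 0), c(1, 2)), "undefined metric")
})

test_that("error inflation never improves either metric", {
  set.seed(13)
  for (i in 1:20) {
    a <- rpois(12, 20) + 1
    p <- a + rnorm(12)
    worse <- a + 2.5 * (p - a)
    expect_gte(median_absolute_error(a, worse), median_absolute_error(a, p))
    expect_gte(median_absolute_percentage_error(a, worse),
               median_absolute_percentage_error(a, p))
  }
})

test_that("a clairvoyant model scores zero and results are deterministic", {
  cfg <- series_generator_config(seed = 61)
  s <- generate_monthly_series(cfg)
  oracle <- wrap_external_forecaster("clairvoyant", function(train, horizon, seed) {
    start <- match(max(train$month), s$month)
    list(point = s$count[start + seq_len(horizon)])
  })
  plan <- cv_plan(n_repetitions = 5, seed = 3)
  tab <- cross_validate(s, c(builtin_forecasters("random_walk"), list(oracle)), plan)
  expect_equal(tab$mae[tab$model == "clairvoyant"], rep(0, 4))
  expect_equal(tab$mape_percent[tab$model == "clairvoyant"], rep(0, 4))

  tab2 <- cross_validate(s, c(builtin_forecasters("random_walk"), list(oracle)), plan)
  expect_equal(as.data.frame(tab), as.data.frame(tab2))

  # listing order does not change any score
  tab3 <- cross_validate(s, c(list(oracle), builtin_forecasters("random_walk")), plan)
  key <- function(t) t[order(t$model, t$horizon_months), c("mae", "mape_percent", "sd")]
  expect_equal(key(as.data.frame(tab)), key(as.data.frame(tab3)), ignore_attr = TRUE)
})

test_that("model failures are excluded with a message, not silently dropped", {
  s <- generate_monthly_series(series_generator_config(seed = 71))
  flaky <- wrap_external_forecaster("flaky", function(train, horizon, seed) {
    stop("deliberate failure")
  })
  plan <- cv_plan(n_repetitions = 2, seed = 9)
  expect_message(
    tab <- cross_validate(s, c(builtin_forecasters("random_walk"), list(flaky)), plan),
    "failed")
  expect_equal(unique(tab$n_failures[tab$model == "flaky"]), 10L)
  expect_true(all(is.na(tab$mae[tab$model == "flaky"]) | tab$n_evaluations[tab$model == "flaky"] == 0))
})

test_that("model comparison reports ratios and sign-flip p-values", {
  s <- generate_monthly_series(series_generator_config(seed = 81))
  base <- builtin_forecasters("historical_average")
  clone <- wrap_external_forecaster("clone", function(train, horizon, seed) {
    historical_average_forecast(train, horizon)
  })
  halver <- wrap_external_forecaster("halver", function(train, horizon, seed) {
    start <- match(max(train$month), s$month)
    truth <- s$count[start + seq_len(horizon)]
    ha <- historical_average_forecast(train, horizon)$point
    list(point = truth + 0.5 * (ha - truth))   # errors exactly halved
  })
  plan <- cv_plan(n_repetitions = 4, seed = 15)
  tab <- cross_validate(s, c(base, list(clone, halver)), plan)
  cmp <- compare_models(tab, "historical_average", n_permutations = 2000, seed = 1)

  clone_rows <- cmp[cmp$model == "clone", ]
  expect_equal(clone_rows$mae_ratio, rep(1, 4), tolerance = 1e-12)
  expect_true(all(clone_rows$p_value > 0.99))

  halver_rows <- cmp[cmp$model == "halver", ]
  expect_equal(halver_rows$mae_ratio, rep(0.5, 4), tolerance = 1e-10)
  expect_true(all(halver_rows$p_value < 0.01))

  expect_error(compare_models(tab, "no_such_model"), "not in the score table")
  cmp2 <- compare_models(tab, "historical_average", n_permutations = 2000, seed = 1)
  expect_equal(cmp, cmp2)
})
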
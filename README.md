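# refcast

Forecasting and period comparison of acute referral time series.

Specialist surgical centres receive a steady stream of acute referrals whose
monthly volume trends upward, cycles mildly with the season, and jumps around
from month to month. Planning staffing and theatre capacity around such a
series needs three things: a forecaster that handles trend, seasonality and
volatility automatically; an honest out-of-sample evaluation against naive
baselines; and a statistical comparison of referral patterns between
clinically meaningful periods (before, during and after the COVID-19 lockdown,
and a forecast year). `refcast` implements all three for monthly referral
counts, together with a synthetic-data generator so the whole pipeline can be
exercised and tested without access to any real patient-level data.

## The model

The headline forecaster is an **STL–ARIMA pipeline**. The count series
\(y_t\) is first decomposed additively by seasonal-trend decomposition using
loess (STL, period 12):

    y_t = S_t + T_t + R_t

where the remainder is defined by exact subtraction. The trend component is
checked for stationarity with an augmented Dickey–Fuller regression. Each
component is then modelled separately: the seasonal component is extended by
repeating its last observed cycle, while the trend and remainder each receive
an ARIMA(p,d,q) model whose order is chosen by an automated grid search
(default p,q ≤ 3, d ≤ 2) minimising the Akaike Information Criterion,

    AIC = 2k − 2 log L,   k = p + q + 2,

with the exact Gaussian likelihood computed by a Kalman filter on the ARMA
state-space form. The component forecasts are summed, and interval variances
are combined across components under an independence assumption.

Around the forecaster sit:

* two baselines — the random-walk (last value) and historical-average (full
  mean) forecasts — plus a from-scratch additive regression comparator
  (piecewise-linear trend with shrunken changepoints, yearly Fourier
  seasonality, declared custom windows such as a lockdown period), and an
  adapter socket for external models;
* **blocked cross-validation**: randomly placed, non-overlapping
  train-then-test blocks (default five 15-month training windows, horizons
  1/3/6/12 months, 1000 re-randomised repetitions) scored by the median
  absolute error and the median absolute percentage error;
* the **period-comparison battery**: Pearson chi-square on contingency
  tables, Kruskal–Wallis with Dunn post-hoc tests, Bartlett and
  Kolmogorov–Smirnov checks, and Benjamini–Hochberg false-discovery-rate
  correction — all implemented in closed form and verified against
  established implementations in the test suite.

## A worked example

```r
library(refcast)

# 89 months of synthetic referrals (June 2014 - October 2021): upward trend,
# mild yearly cycle, a candidate rate dip over the lockdown window
series <- generate_monthly_series(series_generator_config(seed = 1))
series
#> <monthly_series> 89 months: 2014-06 .. 2021-10
#>   counts: min 1, median 7, max 22

fc <- stl_arima_forecast(series, horizon = 12)
round(mean(fc$point), 1)
#> [1] 20.1
round(mean(tail(series$count, 12)), 1)
#> [1] 14.1
```

The twelve forecast months average 20.1 referrals against 14.1 over the last
observed year: the fitted upward trend continues into the forecast. Model
comparison by blocked cross-validation:

```r
mods <- builtin_forecasters(c("stl_arima", "random_walk"), grid = arima_grid(2, 1, 2))
plan <- cv_plan(n_folds = 3, train_window_months = 36, n_repetitions = 50, seed = 3)
long <- generate_monthly_series(series_generator_config(
  start_month = "2010-01", n_months = 120, shock_window = NULL, seed = 101))
cross_validate(long, mods, plan)
#> <score_table> blocked cross-validation scores
#>        model horizon_months   mae mape_percent    sd n_evaluations n_failures
#>  random_walk              1 3.500        25.46 3.003           150          0
#>  random_walk              3 4.000        29.63 2.587           150          0
#>  random_walk              6 3.500        33.52 2.381           150          0
#>  random_walk             12 4.000        32.78 2.036           150          0
#>    stl_arima              1 2.869        25.23 3.492           150          0
#>    stl_arima              3 3.122        26.09 1.886           150          0
#>    stl_arima              6 3.249        26.93 1.412           150          0
#>    stl_arima             12 3.352        24.85 1.170           150          0
```

The pipeline's one-year median absolute percentage error (24.9%) undercuts
the naive baseline's (32.8%), and it is the only model here inside the
commonly quoted 25% acceptability band at one year. For the period
statistics, a grade-by-period contingency table is tested directly:

```r
grades <- matrix(c(23, 50, 8, 30, 22, 10, 31, 28, 6), nrow = 3,
                 dimnames = list(c("intern", "resident", "attending"),
                                 c("pre_covid", "covid", "post_covid")))
pearson_chi_square(grades)[c("statistic", "df", "p_value")]
#> $statistic  11.87507
#> $df         4
#> $p_value    0.01830915
```

An end-to-end run (`run_full_analysis()`, or the `inst/scripts/refcast`
command-line wrapper) writes the series, decomposition, forecast, score table,
cohort summary and a checksummed manifest to an output directory,
reproducibly for a fixed seed.

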
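---
title: "Methods: forecasting and period comparison of acute referral series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forecasting and period comparison of acute referral series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refcast)
```

This vignette is the package's own account of the models it implements, the
choices that were genuinely open, and what its tests do and do not establish.

## The data and what the generator emulates

The unit of analysis is a monthly count of acute referrals to a specialist
centre. `series_generator_config()` encodes the stylised facts the analysis
assumes: a log-linear rate

$$\log \mu_t = \beta_0 + \beta_1 t + \textstyle\sum_k [a_k \cos(2\pi k t/12) +
b_k \sin(2\pi k t/12)] + \delta\,\mathbf{1}\{t \in W\}$$

with Poisson (default) or negative-binomial counts. The defaults describe an
89-month service history (June 2014 to October 2021): a starting rate of
about 3 referrals per month (`baseline_log_rate = log(3)`), growth of 1.8%
per month on the log scale (`trend_per_month = 0.018`, which carries the
median monthly volume from the low single digits into the teens over seven
years), one yearly Fourier harmonic of modest amplitude (0.10 cosine, 0.05
sine — monthly clinical volumes cycle, but weakly), and a candidate
multiplicative dip of 10% (`shock_log_effect = log(0.9)`) over the UK
lockdown window, March 2020 to February 2021. The dip is deliberately small:
the analysis this package supports found no significant reduction in acute
referrals during that window, so the generator's default perturbation is of
the magnitude that a test *should not* reliably flag.

The record-level generator draws referral dates uniformly within a period
and attributes (referrer grade, urgency, Glasgow Coma Score, symptom
duration, site) from per-period categorical profiles whose defaults resemble
the published marginals of a pituitary referral cohort: grades roughly
27/58/10/5% intern/resident/attending/other before the pandemic, urgency
70:30 urgent:emergency, GCS concentrated at 15, log-normal symptom durations
with a median near a week, and 48 referring sites with geometrically
decaying volume. Noise model and site-volume decay are package choices — the
source tables report only medians, IQRs and percentage splits.

What the generator does **not** emulate: day-of-week or holiday structure
(referral dates are uniform within periods), correlation between attributes
(grade and urgency are drawn independently), drift in the site mix, and
record-level linkage between the count series and the record table beyond
their period totals. Passing tests therefore demonstrate that the pipeline's
machinery is correct under its own assumptions, not that real referral data
satisfy those assumptions.

## STL decomposition

`stl_decompose()` implements the classic iterative procedure: inner-loop
cycles of detrending, loess smoothing of each cycle-subseries (extended one
period at each end), a low-pass filter (two moving averages of length 12,
one of length 3, then a loess), deseasonalising, and a trend loess; an
optional outer loop downweights outlying remainders with bisquare weights.
The remainder is *defined* as input minus seasonal minus trend, so
additivity is an identity rather than an approximation — a property the test
suite asserts on every input it touches.

The source analysis names the method but none of its parameters, so the
defaults here are the classic ones: seasonal window 13 at degree 0 (a nearly
periodic seasonal component is appropriate for seven years of monthly
counts), trend window $\lceil 1.5 p / (1 - 1.5/13)\rceil$ rounded up to odd
(21 for monthly data), low-pass window 13, two inner and zero outer
iterations (counts of this size rarely contain the gross outliers the robust
loop exists for). All are overridable. The implementation is verified
against an established STL implementation on random series: component-wise
RMSE below 5% of the series standard deviation, typically below 1%.

The stationarity check on the trend is an augmented Dickey–Fuller
regression with a constant; the lag order follows Schwert's rule
$\lfloor 12 (n/100)^{1/4}\rfloor$ and the critical values are MacKinnon's
finite-sample response surface. ADF (rather than KPSS) was chosen so that
"stationary" is the rejection, not the null; with series of this length the
test is a coarse diagnostic either way, and its verdict is recorded on the
forecast object rather than used to switch models. The reported p-value is
an interpolation between the tabulated 1/5/10% points and is a bound outside
that range.

## ARIMA engine

`fit_arima()` maximises the exact Gaussian likelihood of an ARMA(p,q) model
with intercept, after d-fold differencing, with the innovation variance
concentrated out. The likelihood is computed by a Kalman filter on Harvey's
state-space form (compiled, with the stationary initial covariance solved
from the Lyapunov equation); stationarity and invertibility are enforced by
parametrising both polynomial coefficient vectors through tanh-transformed
partial autocorrelations; starting values come from a Hannan–Rissanen
two-step regression; the optimiser is BFGS with relative tolerance 1e-8 and
at most 500 iterations. On fixed test series the coefficients agree with an
established exact-ML implementation to about 1e-4 and the AIC to well under
0.01.

Three conventions deserve a note:

* **Intercept with differencing.** The intercept is retained on the
  differenced scale (where it acts as drift), keeping $k = p + q + 2$ in
  $\mathrm{AIC} = 2k - 2\log L$ uniformly. Drift is what lets the pipeline
  out-forecast a flat random walk on trending series; the no-intercept
  random-walk model is available via `include_mean = FALSE`.
* **Small samples.** The evaluation design trains on 15-month windows, so
  the fitter's hard floor is identifiability ($n - d \ge p + q + 3$) with a
  warning, rather than an error, below the comfortable
  $\max(3(p+q+1), 20)$ level. The automated grid simply skips orders that
  cannot be fitted.
* **Grid search.** `auto_arima_grid_search()` fits every order in the grid
  (default $p,q \le 3$, $d \le 2$), skips failures, and returns the minimal
  plain AIC, ties broken by fewest parameters then lexicographically. Two
  caveats are documented rather than patched: AIC values for different $d$
  are computed on different effective samples and are therefore only
  approximately comparable; and on pure white noise a full-grid minimal-AIC
  search retains an overfitted order in a substantial minority of draws
  (roughly a third — an established implementation searched over the same
  grid behaves the same way). That is the statistical price of AIC, which
  trades selection consistency for predictive loss; the package reports the
  measured selection rate rather than pretending otherwise.

Forecasts propagate the final Kalman state (exact conditional means),
integrate back through the differences, and take interval half-widths
$z_{(1+\gamma)/2}\,\sigma\sqrt{\sum_{j<h}\psi_j^2}$ from the
$\psi$-weights of the full ARIMA operator. One-step 95% intervals on
simulated AR(1) data cover about 95% empirically (the suite requires
92–98%).

## The composed forecaster

`stl_arima_forecast()` decomposes (period 12), forecasts the seasonal
component by repeating its last full cycle — the standard convention when a
decomposition, not a seasonal ARIMA, carries the seasonality — and gives the
trend and remainder each their own grid-searched ARIMA. Component interval
variances are summed as if the component forecasts were independent; STL
components are not exactly orthogonal, so the resulting band is an
approximation (typically slightly conservative for the remainder-dominated
horizons). Series shorter than two seasonal cycles fall back, with a
warning, to a single auto-ARIMA on the raw counts; horizons beyond two
cycles draw an extrapolation warning.

## Comparators

The two baselines are deliberately the conventional definitions — last
observed value with $\sigma\sqrt{h}$ intervals, and full-history arithmetic
mean with $\sigma\sqrt{1 + 1/n}$ intervals — because the analysis being
reproduced names them without defining them. Windowed averages and drifted
random walks are easy to add through the adapter interface but are not the
defaults.

The additive regression comparator fits, by penalised least squares, a
piecewise-linear trend (10 candidate changepoints evenly spaced over the
first 80% of the training span, slope changes shrunk by an L1-style penalty
approximated with iteratively reweighted ridge steps), a yearly Fourier
block (order 3 by default; the order-6 sine column is dropped as it
vanishes at integer months), and indicator effects over declared windows
such as a lockdown period. Growth is linear, not logistic: referral counts
have no natural capacity. Weekly seasonality, which the model family this
emulates would normally include, is omitted because monthly aggregation
cannot express it. Intervals are Gaussian with constant half-width from the
residual standard deviation — cruder than the simulation-based bands of the
inspiration, and documented as such.

`wrap_external_forecaster()` is the socket through which an externally
trained model (for instance a convolutional–recurrent network) can enter
the evaluation; the contract is checked at every call (exact horizon,
determinism under a fixed seed), and no neural network is implemented here.

## Evaluation design

"Blocked cross-validation, randomly divided into five folds, respecting
temporal order" is internally tense: random division and temporal blocking
pull in opposite directions. The reading implemented is: five disjoint test
blocks, each of length `max(horizons)` so one fold serves all horizons, each
immediately preceded by its own training window, with the slack placed
uniformly at random between the blocks and re-randomised on every
repetition — this is what makes 1000 repetitions informative rather than
redundant. The minimal feasible length is `train + n_folds * max(horizons)`;
at exactly that length there is a single layout and every seed returns it.
A leakage audit (no training index at or beyond its fold's first test
index) runs over every fold of every repetition in the test suite.

Scores are medians of absolute (and percentage) errors — medians because
referral-count errors are skewed with occasional large misses. The score of
a (model, horizon) cell is the median over repetitions and folds of the
fold-level medians; the dispersion column is the standard deviation of
those fold-level values. Zero-actual months are skipped in the percentage
metric with a logged count (an epsilon-padded alternative would manufacture
arbitrary percentages). Model failures on a fold are counted and excluded,
never silently dropped. Comparison against baselines uses a paired
sign-flip permutation test on fold-level errors (the comparison test for
the published score tables is unstated; a paired permutation test is the
assumption-light choice at these sample sizes).

## Period statistics

The battery mirrors the published analysis: Kruskal–Wallis (midranks, tie
correction) with Dunn post-hoc z tests under Benjamini–Hochberg correction
for monthly volumes, sites, GCS and symptom duration; Pearson chi-square
without continuity correction for the urgency split and the grade table.
"No continuity correction" is not a preference but a requirement: the
published grade-table statistics (11.9 overall, 9.7 pre-vs-lockdown, 6.0
pre-vs-post) are reproduced exactly from the printed counts only without
Yates' adjustment. Pairwise grade comparisons are computed on raw subtables
and only their p-values enter the BH family; the families of different test
batteries are kept separate. Grades aggregate as foundation-year → intern,
SHO/SpR/registrar → resident, consultant → attending, everything else
excluded — the three-category table is the one the published counts
support. The KS normality check uses parameters estimated from the sample
with the asymptotic Kolmogorov p-value; without a Lilliefors adjustment it
is conservative, which the return value notes.

## Reproducibility and problem sizes

Every stochastic routine takes or derives a seed; the pipeline runner
derives per-stage substreams from one global seed so stages can be re-run in
isolation, and its manifest records an md5 checksum per artifact. The test
suite and the acceptance script scale the heavier simulations to sizes a
single core handles in a couple of minutes — 100 replicates for recovery
rates, 500 for interval coverage, 50 repetitions for the pipeline-vs-
baseline comparison on a 120-month series with 36-month training windows
(long enough for the STL step to run rather than fall back), and 100-vs-1000
repetitions for the stability check on the 89-month default series. These
sizes are the package's own choices; the estimated rates carry Monte-Carlo
error of a few percentage points, and the assertions leave room for it.

## Known limitations

* AIC values across differencing orders are only approximately comparable;
  a unit-root pre-test (as some automated selectors use) would be the
  alternative convention.
* The pipeline's interval variance ignores dependence between STL
  components and the uncertainty of the seasonal-naive extension.
* The additive comparator's L1 approximation by reweighted ridge does not
  produce exact zeros in the changepoint slopes, only strong shrinkage.
* The ADF p-value is a tabulated-interpolation bound, not a smooth
  function.
* With 15-month training windows the composed forecaster always operates in
  its documented raw-ARIMA fallback; conclusions about the full STL
  pipeline need training windows of at least two seasonal cycles.
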
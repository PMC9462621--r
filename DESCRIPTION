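Package: refcast
Title: Forecasting and Period Comparison of Acute Referral Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing monthly counts of acute specialist referrals:
    a synthetic-data generator for referral records and monthly count series,
    seasonal-trend decomposition by loess (STL) with an augmented Dickey-Fuller
    stationarity check, exact-likelihood ARIMA fitting with AIC-based automated
    order selection, the composed STL-ARIMA forecaster, naive and additive
    regression comparators, blocked time-series cross-validation scored by
    median absolute and median absolute percentage error, and the
    period-comparison statistics battery (Pearson chi-square, Kruskal-Wallis,
    Dunn post-hoc tests, Bartlett and Kolmogorov-Smirnov checks,
    Benjamini-Hochberg correction).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
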
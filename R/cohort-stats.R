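#' Pearson chi-square test of independence on a contingency table
#'
#' Plain Pearson statistic, no continuity correction:
#' `sum((observed - expected)^2 / expected)` with expected counts from the
#' row and column margins, `(r-1)(c-1)` degrees of freedom, upper-tail
#' chi-square p-value.
#'
#' @param counts Non-negative integer matrix, at least 2x2.
#' @return List with `statistic`, `df`, `p_value`, `expected`.
#' @export
pearson_chi_square <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L) {
    stop("the contingency table needs at least 2 rows and 2 columns", call. = FALSE)
  }
  if (any(counts < 0) || anyNA(counts)) {
    stop("counts must be non-negative and complete", call. = FALSE)
  }
  rs <- rowSums(counts); cs <- colSums(counts)
  if (any(rs == 0) || any(cs == 0)) {
    stop("degenerate table: a zero row or column margin makes expected counts zero",
         call. = FALSE)
  }
  N <- sum(counts)
  expected <- outer(rs, cs) / N
  statistic <- sum((counts - expected)^2 / expected)
  df <- (nrow(counts) - 1L) * (ncol(counts) - 1L)
  list(statistic = statistic, df = df,
       p_value = stats::pchisq(statistic, df, lower.tail = FALSE),
       expected = expected)
}

#' Kruskal-Wallis rank-sum test
#'
#' `H = 12 / (N(N+1)) * sum(R_g^2 / n_g) - 3(N+1)` on midranks, divided by
#' the tie-correction factor `1 - sum(t^3 - t) / (N^3 - N)`; p-value from a
#' chi-square with `g - 1` degrees of freedom. When every observation is
#' identical the statistic is defined as 0 with p = 1 (there is no evidence
#' of any difference, and the tie correction degenerates).
#'
#' @param groups List of at least two non-empty numeric vectors.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("`groups` must be a list of at least two vectors", call. = FALSE)
  }
  sizes <- lengths(groups)
  if (any(sizes == 0L)) stop("every group must be non-empty", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  df <- length(groups) - 1L
  if (max(x) == min(x)) {
    return(list(statistic = 0, df = df, p_value = 1))
  }
  r <- rank(x)  # midranks
  idx <- rep(seq_along(groups), sizes)
  R <- tapply(r, idx, sum)
  H <- 12 / (N * (N + 1)) * sum(R^2 / sizes) - 3 * (N + 1)
  ties <- table(x)
  H <- H / (1 - sum(ties^3 - ties) / (N^3 - N))
  list(statistic = unname(H), df = df,
       p_value = stats::pchisq(H, df, lower.tail = FALSE))
}

#' Dunn's post-hoc pairwise comparisons
#'
#' Rank-based pairwise z statistics on the joint midranks,
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))` with the
#' tie term `T = sum(t^3 - t) / (12 (N - 1))`, two-sided normal p-values,
#' optionally adjusted by [benjamini_hochberg()].
#'
#' @param groups Named (or unnamed) list of at least three numeric vectors.
#' @param correction `"benjamini_hochberg"` or `"none"`.
#' @return Data frame: `group_i`, `group_j`, `z`, `p_raw`, `p_adjusted`.
#' @export
dunn_posthoc <- function(groups, correction = c("benjamini_hochberg", "none")) {
  correction <- match.arg(correction)
  if (!is.list(groups) || length(groups) < 3L) {
    stop("post-hoc comparisons need at least 3 groups", call. = FALSE)
  }
  sizes <- lengths(groups)
  if (any(sizes == 0L)) stop("every group must be non-empty", call. = FALSE)
  labels <- names(groups)
  if (is.null(labels)) labels <- paste0("group", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  r <- rank(x)
  idx <- rep(seq_along(groups), sizes)
  rbar <- tapply(r, idx, mean)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(length(groups), 2L)
  z <- p_raw <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / sizes[i] + 1 / sizes[j]))
    z[k] <- (rbar[i] - rbar[j]) / se
    p_raw[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  p_adj <- if (correction == "benjamini_hochberg") {
    benjamini_hochberg(p_raw)$adjusted
  } else p_raw
  data.frame(group_i = labels[pairs[1L, ]], group_j = labels[pairs[2L, ]],
             z = z, p_raw = p_raw, p_adjusted = p_adj,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up false-discovery-rate procedure
#'
#' Rejects all ordered p-values `p_(i)` with `i <= max{k : p_(k) <= k q/m}`;
#' adjusted values are the standard monotone cumulative-minimum transform
#' `min_k>=i (m p_(k) / k)` capped at 1, so `rejected == (adjusted <= q)`.
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @param q Target false-discovery rate.
#' @return List with logical `rejected` and numeric `adjusted`, both in the
#'   input order.
#' @export
benjamini_hochberg <- function(p_values, q = 0.05) {
  p <- as.numeric(p_values)
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj_sorted <- rev(cummin(rev(pmin(1, m * ranked / seq_len(m)))))
  adjusted <- numeric(m)
  adjusted[o] <- adj_sorted
  k <- which(ranked <= seq_len(m) * q / m)
  rejected <- logical(m)
  if (length(k)) rejected[o[seq_len(max(k))]] <- TRUE
  list(rejected = rejected, adjusted = adjusted)
}

#' Kolmogorov-Smirnov check against a fitted normal
#'
#' KS distance of the sample against a normal with the sample mean and
#' standard deviation; the p-value uses the asymptotic Kolmogorov
#' distribution. Because the reference parameters are estimated from the
#' same data, the p-value is conservative (large-sample approximation, no
#' Lilliefors adjustment) — noted in the returned `note`.
#'
#' @param sample Numeric vector, length >= 5.
#' @return List with `statistic` (D), `p_value`, `note`.
#' @export
ks_normality <- function(sample) {
  x <- sort(as.numeric(sample))
  n <- length(x)
  if (n < 5L) stop("KS normality check needs at least 5 observations", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) stop("degenerate input: zero variance", call. = FALSE)
  z <- stats::pnorm((x - mean(x)) / s)
  D <- max(pmax(seq_len(n) / n - z, z - (seq_len(n) - 1L) / n))
  list(statistic = D, p_value = kolmogorov_sf(sqrt(n) * D),
       note = "reference parameters estimated from the sample; p-value is the asymptotic Kolmogorov approximation")
}

# Survival function of the Kolmogorov distribution at t (asymptotic series).
kolmogorov_sf <- function(t) {
  if (t < 1e-8) return(1)
  k <- 1:100
  min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))))
}

#' Bartlett's test of homogeneity of variances
#'
#' Closed form: with `k` groups, sizes `n_i`, variances `s_i^2` and pooled
#' variance `sp^2`,
#' `X^2 = ((N-k) ln sp^2 - sum((n_i-1) ln s_i^2)) / C` with the usual
#' correction factor `C`; chi-square p with `k - 1` df.
#'
#' @param groups List of numeric vectors (each length >= 2, positive
#'   variance).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
bartlett_test <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("`groups` must be a list of at least two vectors", call. = FALSE)
  }
  ni <- lengths(groups)
  if (any(ni < 2L)) stop("every group needs at least 2 observations", call. = FALSE)
  vi <- vapply(groups, stats::var, numeric(1))
  if (any(vi <= 0)) {
    stop("degenerate input: a group has zero variance", call. = FALSE)
  }
  k <- length(groups)
  N <- sum(ni)
  sp2 <- sum((ni - 1) * vi) / (N - k)
  stat <- ((N - k) * log(sp2) - sum((ni - 1) * log(vi))) /
    (1 + (sum(1 / (ni - 1)) - 1 / (N - k)) / (3 * (k - 1)))
  list(statistic = stat, df = k - 1L,
       p_value = stats::pchisq(stat, k - 1L, lower.tail = FALSE))
}

#' Analysis period definitions
#'
#' The default four comparison windows: a pre-pandemic year, the UK
#' lockdown-restriction year, the post-restriction months with observed
#' data, and the forecast year beyond the data.
#'
#' @param names,starts,ends Equal-length vectors defining ordered,
#'   non-overlapping periods.
#' @return Data frame with columns `name`, `start`, `end` (first-of-month
#'   `Date`s, inclusive).
#' @export
period_definitions <- function(names = c("pre_covid", "covid", "post_covid", "forecast"),
                               starts = c("2019-03", "2020-03", "2021-03", "2021-10"),
                               ends = c("2020-02", "2021-02", "2021-09", "2022-09")) {
  starts <- as_month(starts); ends <- as_month(ends)
  if (length(names) != length(starts) || length(starts) != length(ends)) {
    stop("names, starts and ends must have equal length", call. = FALSE)
  }
  if (any(ends < starts)) stop("each period must end on or after its start", call. = FALSE)
  if (length(starts) > 1L && any(starts[-1L] <= ends[-length(ends)])) {
    stop("periods must be ordered and non-overlapping", call. = FALSE)
  }
  data.frame(name = names, start = starts, end = ends, stringsAsFactors = FALSE)
}

# Referrer grade aggregation used by the grade contingency table:
# foundation-years are interns, SHO/SpR/registrars residents, consultants
# attendings; anything else is excluded from the grade table.
aggregate_grade <- function(grade) {
  g <- tolower(as.character(grade))
  out <- rep(NA_character_, length(g))
  out[g %in% c("intern", "fy", "fy1", "fy2", "foundation")] <- "intern"
  out[g %in% c("resident", "sho", "spr", "registrar", "st")] <- "resident"
  out[g %in% c("attending", "consultant")] <- "attending"
  out
}

#' Per-period cohort summary and statistical battery
#'
#' For each period: median (IQR) monthly referral volume, median (IQR)
#' unique referring sites per month, urgent:emergency percentage split,
#' median (IQR) symptom duration, and grade counts
#' (intern/resident/attending, other grades excluded). Periods with no data
#' are reported with missing values rather than dropped. The battery then
#' compares periods: Kruskal-Wallis (with Dunn post-hoc under
#' Benjamini-Hochberg correction) on monthly volumes, unique monthly sites,
#' GCS and symptom duration; chi-square on the urgency split; and the grade
#' table chi-square (overall plus pairwise period subtables on the raw
#' counts, with Benjamini-Hochberg correction applied to the pairwise
#' p-values only).
#'
#' @param records Referral-record data frame.
#' @param series A [monthly_series()] of monthly volumes; may extend into a
#'   forecast period that has no records.
#' @param periods A [period_definitions()] data frame.
#' @return List with `summary` (one row per period), `grade_table` and
#'   `tests`.
#' @export
period_summary <- function(records, series, periods = period_definitions()) {
  records <- validate_referral_records(records)
  rec_month <- as_month(records$referral_date)
  per_rec <- lapply(seq_len(nrow(periods)), function(i) {
    records[rec_month >= periods$start[i] & rec_month <= periods$end[i], , drop = FALSE]
  })
  per_vol <- lapply(seq_len(nrow(periods)), function(i) {
    series$count[series$month >= periods$start[i] & series$month <= periods$end[i]]
  })
  iqr_text <- function(x) {
    if (!length(x)) return(NA_character_)
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    sprintf("%g (%g-%g)", q[2L], q[1L], q[3L])
  }
  monthly_sites <- function(rec) {
    if (!nrow(rec)) return(numeric(0))
    tapply(rec$site_id, format(as_month(rec$referral_date), "%Y-%m"),
           function(s) length(unique(s)))
  }
  summary <- do.call(rbind, lapply(seq_len(nrow(periods)), function(i) {
    rec <- per_rec[[i]]
    vols <- per_vol[[i]]
    urg <- if (nrow(rec)) mean(rec$urgency == "urgent") else NA_real_
    data.frame(
      period = periods$name[i],
      n_months = length(vols),
      n_records = nrow(rec),
      monthly_volume = iqr_text(vols),
      unique_monthly_sites = iqr_text(as.numeric(monthly_sites(rec))),
      urgent_pct = if (is.na(urg)) NA_real_ else round(100 * urg, 1),
      emergency_pct = if (is.na(urg)) NA_real_ else round(100 * (1 - urg), 1),
      symptom_duration = iqr_text(rec$symptom_duration_days),
      stringsAsFactors = FALSE)
  }))

  has_records <- vapply(per_rec, nrow, integer(1)) > 0L
  has_vols <- lengths(per_vol) > 0L

  grade_table <- NULL
  grade_periods <- which(has_records)
  if (length(grade_periods) >= 2L) {
    cols <- lapply(grade_periods, function(i) {
      g <- aggregate_grade(per_rec[[i]]$grade)
      table(factor(g, levels = c("intern", "resident", "attending")))
    })
    grade_table <- do.call(cbind, cols)
    colnames(grade_table) <- periods$name[grade_periods]
  }

  tests <- list()
  kw_battery <- function(values_by_period) {
    keep <- lengths(values_by_period) > 0L
    if (sum(keep) < 2L) return(NULL)
    groups <- stats::setNames(values_by_period[keep], periods$name[keep])
    out <- list(kruskal_wallis = kruskal_wallis(groups))
    if (length(groups) >= 3L) out$dunn <- dunn_posthoc(groups)
    out
  }
  tests$monthly_volume <- kw_battery(per_vol)
  tests$unique_monthly_sites <- kw_battery(lapply(per_rec, function(r) as.numeric(monthly_sites(r))))
  tests$gcs <- kw_battery(lapply(per_rec, function(r) as.numeric(r$gcs)))
  tests$symptom_duration <- kw_battery(lapply(per_rec, function(r) as.numeric(r$symptom_duration_days)))

  urg_periods <- which(has_records)
  if (length(urg_periods) >= 2L) {
    urg_tab <- do.call(cbind, lapply(urg_periods, function(i) {
      table(factor(per_rec[[i]]$urgency, levels = c("urgent", "emergency")))
    }))
    colnames(urg_tab) <- periods$name[urg_periods]
    tests$urgency <- tryCatch(pearson_chi_square(urg_tab), error = function(e) NULL)
  }
  if (!is.null(grade_table)) {
    overall <- tryCatch(pearson_chi_square(grade_table), error = function(e) NULL)
    pairwise <- NULL
    if (!is.null(overall) && ncol(grade_table) >= 3L) {
      pr <- utils::combn(ncol(grade_table), 2L)
      rows <- lapply(seq_len(ncol(pr)), function(k) {
        sub <- grade_table[, pr[, k], drop = FALSE]
        res <- tryCatch(pearson_chi_square(sub), error = function(e) NULL)
        if (is.null(res)) return(NULL)
        data.frame(period_i = colnames(grade_table)[pr[1L, k]],
                   period_j = colnames(grade_table)[pr[2L, k]],
                   statistic = res$statistic, df = res$df, p_raw = res$p_value,
                   stringsAsFactors = FALSE)
      })
      pairwise <- do.call(rbind, rows)
      if (!is.null(pairwise) && nrow(pairwise)) {
        pairwise$p_adjusted <- benjamini_hochberg(pairwise$p_raw)$adjusted
      }
    }
    tests$grade <- list(overall = overall, pairwise = pairwise)
  }
  list(summary = summary, grade_table = grade_table, tests = tests)
}
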
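#' Monthly referral-count series
#'
#' A `monthly_series` is the universal forecasting input of the package: an
#' ordered, gap-free sequence of calendar months with a non-negative count per
#' month. Months are stored as first-of-month `Date`s; a referral belongs to
#' the month containing its date.
#'
#' @param months `Date` vector of strictly increasing, consecutive calendar
#'   months (any day-of-month is accepted and snapped to the first).
#' @param counts Non-negative numeric vector, same length as `months`.
#'
#' @return An object of class `monthly_series`: a data frame with columns
#'   `month` (`Date`, first of month) and `count`.
#' @export
#' @examples
#' monthly_series(seq(as.Date("2020-01-01"), by = "month", length.out = 3),
#'                c(4, 7, 5))
monthly_series <- function(months, counts) {
  months <- as_month(months)
  counts <- as.numeric(counts)
  if (length(months) != length(counts)) {
    stop("`months` and `counts` must have the same length", call. = FALSE)
  }
  if (length(months) == 0L) {
    stop("a monthly series must contain at least one month", call. = FALSE)
  }
  if (anyNA(months) || anyNA(counts)) {
    stop("months and counts must not contain missing values", call. = FALSE)
  }
  if (any(counts < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (length(months) > 1L) {
    gaps <- month_diff(months[-1L], months[-length(months)])
    if (any(gaps != 1L)) {
      stop("months must be strictly increasing and gap-free (consecutive calendar months)",
           call. = FALSE)
    }
  }
  structure(
    data.frame(month = months, count = counts),
    class = c("monthly_series", "data.frame")
  )
}

#' @export
print.monthly_series <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("<monthly_series> %d months: %s .. %s\n", n,
              format(x$month[1L], "%Y-%m"), format(x$month[n], "%Y-%m")))
  cat(sprintf("  counts: min %s, median %s, max %s\n",
              format(min(x$count)), format(stats::median(x$count)),
              format(max(x$count))))
  invisible(x)
}

#' @export
as.ts.monthly_series <- function(x, ...) {
  first <- x$month[1L]
  stats::ts(x$count, start = c(as.integer(format(first, "%Y")),
                               as.integer(format(first, "%m"))),
            frequency = 12)
}

# Snap dates (or "YYYY-MM" strings) to first-of-month Date; malformed
# strings become NA rather than an error so callers can report row numbers.
as_month <- function(x) {
  if (is.character(x)) {
    x <- ifelse(grepl("^\\d{4}-\\d{2}$", x), paste0(x, "-01"), x)
    x <- as.Date(x, format = "%Y-%m-%d")
  }
  x <- as.Date(x)
  as.Date(format(x, "%Y-%m-01"))
}

# Number of calendar months from `from` to `to` (vectorised).
month_diff <- function(to, from) {
  to <- as_month(to); from <- as_month(from)
  yt <- as.integer(format(to, "%Y")); mt <- as.integer(format(to, "%m"))
  yf <- as.integer(format(from, "%Y")); mf <- as.integer(format(from, "%m"))
  (yt - yf) * 12L + (mt - mf)
}

# Sequence of n consecutive months starting at `start`.
month_seq <- function(start, n) {
  seq(as_month(start), by = "month", length.out = n)
}

#' Aggregate referral records to a monthly count series
#'
#' Counts records per calendar month over `span`; months with no records are
#' kept with an explicit zero so the resulting series is gap-free. The
#' day-of-month of each referral is discarded at this step.
#'
#' @param records A referral-record data frame (see
#'   [generate_referral_records()] or [read_referrals_csv()]) with a
#'   `referral_date` column.
#' @param span Either `NULL` (span of the data) or a length-2 vector of months
#'   (`Date` or `"YYYY-MM"`) giving the first and last month of the series.
#' @param truncate If `TRUE`, records outside `span` are dropped silently;
#'   if `FALSE` (default), out-of-span records are an error.
#'
#' @return A [monthly_series()].
#' @export
aggregate_records_to_series <- function(records, span = NULL, truncate = FALSE) {
  dates <- as.Date(records$referral_date)
  if (is.null(span)) {
    if (length(dates) == 0L) {
      stop("an explicit `span` is required to aggregate an empty record set",
           call. = FALSE)
    }
    span <- range(as_month(dates))
  }
  if (length(span) != 2L) stop("`span` must be length 2 (first, last month)", call. = FALSE)
  first <- as_month(span[1L]); last <- as_month(span[2L])
  n <- month_diff(last, first) + 1L
  if (n < 1L) stop("empty span: last month precedes first", call. = FALSE)
  months <- month_seq(first, n)
  if (length(dates)) {
    idx <- month_diff(as_month(dates), first) + 1L
    out <- idx < 1L | idx > n
    if (any(out)) {
      if (!truncate) {
        stop(sprintf("%d record(s) fall outside the requested span; use truncate = TRUE to drop them",
                     sum(out)), call. = FALSE)
      }
      idx <- idx[!out]
    }
    counts <- tabulate(idx, nbins = n)
  } else {
    counts <- integer(n)
  }
  monthly_series(months, counts)
}
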
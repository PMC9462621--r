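#' Read a monthly series from CSV
#'
#' Expects a header with columns `month` (`YYYY-MM` or ISO date) and
#' `count`. A gap between consecutive months is an error unless
#' `fill_zero = TRUE`, in which case the missing months are inserted with an
#' explicit zero count.
#'
#' @param path CSV file path.
#' @param fill_zero Insert zero-count rows for missing months.
#' @return A [monthly_series()].
#' @export
read_series_csv <- function(path, fill_zero = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("month", "count")) {
    if (!col %in% names(df)) {
      stop(sprintf("%s: missing required column '%s'", path, col), call. = FALSE)
    }
  }
  months <- as_month(df$month)
  if (anyNA(months)) {
    stop(sprintf("%s: unparseable month in row(s) %s", path,
                 paste(utils::head(which(is.na(months)), 5L), collapse = ", ")),
         call. = FALSE)
  }
  o <- order(months)
  months <- months[o]; counts <- df$count[o]
  gaps <- if (length(months) > 1L) month_diff(months[-1L], months[-length(months)]) else integer(0)
  if (any(gaps != 1L)) {
    if (!fill_zero) {
      stop(sprintf("%s: gap in the monthly series after %s; use fill_zero = TRUE to insert explicit zeros",
                   path, format(months[which(gaps != 1L)[1L]], "%Y-%m")), call. = FALSE)
    }
    full <- month_seq(months[1L], month_diff(months[length(months)], months[1L]) + 1L)
    counts <- ifelse(full %in% months, counts[match(full, months)], 0)
    months <- full
  }
  monthly_series(months, counts)
}

#' Write a monthly series as CSV (`month` as `YYYY-MM`, `count`)
#' @param series A [monthly_series()].
#' @param path Output file path.
#' @export
write_series_csv <- function(series, path) {
  utils::write.csv(data.frame(month = format(series$month, "%Y-%m"),
                              count = series$count),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read referral records from CSV
#'
#' Validates the schema (columns `referral_date`, `grade`, `specialty`,
#' `urgency`, `gcs`, `symptom_duration_days`, `site_id`) and the field
#' invariants (ISO dates, GCS in 3..15, positive symptom duration, binary
#' urgency), reporting offending row numbers.
#'
#' @param path CSV file path.
#' @return A validated referral-record data frame.
#' @export
read_referrals_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_referral_records(df, source = path)
}

#' Write referral records as CSV (dates ISO-8601)
#' @param records Referral-record data frame.
#' @param path Output file path.
#' @export
write_referrals_csv <- function(records, path) {
  records$referral_date <- format(as.Date(records$referral_date), "%Y-%m-%d")
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' End-to-end run configuration
#'
#' @param generator_config A [series_generator_config()] for synthetic
#'   input, or `NULL` when `series_path` is given.
#' @param series_path,records_path Optional CSV inputs replacing the
#'   generators.
#' @param record_profiles List of [period_profile()]s for the record
#'   generator (`NULL` = a default three-period profile set spanning the
#'   comparison windows).
#' @param periods A [period_definitions()] data frame.
#' @param plan A [cv_plan()].
#' @param models Character vector of built-in model names to evaluate.
#' @param horizon Forecast horizon in months.
#' @param grid An [arima_grid()].
#' @param level Forecast interval level.
#' @param seed Global seed; every stage derives its own substream from it.
#' @return A `run_config` list.
#' @export
run_config <- function(generator_config = series_generator_config(),
                       series_path = NULL, records_path = NULL,
                       record_profiles = NULL,
                       periods = period_definitions(),
                       plan = cv_plan(),
                       models = c("stl_arima", "random_walk", "historical_average", "additive"),
                       horizon = 12L, grid = arima_grid(), level = 0.95,
                       seed = 1L) {
  structure(list(generator_config = generator_config,
                 series_path = series_path, records_path = records_path,
                 record_profiles = record_profiles, periods = periods,
                 plan = plan, models = models, horizon = as.integer(horizon),
                 grid = grid, level = level, seed = as.integer(seed)),
            class = "run_config")
}

default_record_profiles <- function(periods) {
  obs <- periods[periods$name != "forecast", , drop = FALSE]
  grade_mix <- list(
    pre_covid = c(intern = 0.27, resident = 0.58, attending = 0.10, other = 0.05),
    covid = c(intern = 0.45, resident = 0.34, attending = 0.16, other = 0.05),
    post_covid = c(intern = 0.45, resident = 0.41, attending = 0.09, other = 0.05))
  urgency_mix <- list(pre_covid = c(urgent = 0.70, emergency = 0.30),
                      covid = c(urgent = 0.65, emergency = 0.35),
                      post_covid = c(urgent = 0.78, emergency = 0.22))
  duration_med <- list(pre_covid = 3, covid = 7, post_covid = 9.5)
  lapply(seq_len(nrow(obs)), function(i) {
    nm <- obs$name[i]
    n_months <- month_diff(obs$end[i], obs$start[i]) + 1L
    period_profile(obs$start[i], obs$end[i], n = 10L * n_months,
                   grade_probs = grade_mix[[nm]] %||% grade_mix$pre_covid,
                   urgency_probs = urgency_mix[[nm]] %||% urgency_mix$pre_covid,
                   symptom_meanlog = log(duration_med[[nm]] %||% 6.5))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis end to end
#'
#' simulate (or read) -> aggregate -> STL decomposition -> STL-ARIMA
#' forecast -> blocked cross-validation of the requested models ->
#' per-period cohort statistics. Writes `series.csv`,
#' `decomposition.csv`, `forecast.csv`, `scores.csv`,
#' `cohort_summary.csv`, `cohort_tests.json` and `manifest.json` (seed,
#' configuration hash and an md5 checksum per emitted file) under
#' `out_dir`. Identical configuration and seed give identical outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_full_analysis <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(name) {
    p <- file.path(out_dir, name)
    paths[[length(paths) + 1L]] <<- p
    p
  }

  # stage 1: obtain the series and records
  series <- if (!is.null(config$series_path)) {
    read_series_csv(config$series_path)
  } else {
    gc_ <- config$generator_config
    gc_$seed <- derive_seed(config$seed, 1L)
    generate_monthly_series(gc_)
  }
  records <- if (!is.null(config$records_path)) {
    read_referrals_csv(config$records_path)
  } else {
    profiles <- config$record_profiles %||% default_record_profiles(config$periods)
    generate_referral_records(period_profiles = profiles,
                              seed = derive_seed(config$seed, 2L))
  }
  write_series_csv(series, emit("series.csv"))
  write_referrals_csv(records, emit("records.csv"))

  # stage 2: decomposition
  dec <- stl_decompose(series)
  write_decomposition_csv(dec, emit("decomposition.csv"))

  # stage 3: forecast
  fc <- suppressWarnings(stl_arima_forecast(series, horizon = config$horizon,
                                            grid = config$grid, level = config$level))
  write_forecast_csv(fc, emit("forecast.csv"))

  # stage 4: evaluation
  scores <- cross_validate(series, builtin_forecasters(config$models, grid = config$grid),
                           config$plan)
  write_scores_csv(scores, emit("scores.csv"))

  # stage 5: cohort statistics; forecast months extend the volume series
  fc_series <- monthly_series(c(series$month, fc$months),
                              c(series$count, pmax(0, round(fc$point))))
  cohort <- period_summary(records, fc_series, config$periods)
  utils::write.csv(cohort$summary, emit("cohort_summary.csv"), row.names = FALSE)
  jsonlite::write_json(
    serialise_tests(cohort),
    emit("cohort_tests.json"), auto_unbox = TRUE, digits = 10, pretty = TRUE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("refcast")),
    seed = config$seed,
    config_hash = unname(config_hash(config)),
    files = lapply(stats::setNames(paths, basename(unlist(paths))), function(p) {
      list(path = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

serialise_tests <- function(cohort) {
  list(tests = cohort$tests,
       grade_table = if (is.null(cohort$grade_table)) NULL else
         as.data.frame.matrix(cohort$grade_table))
}

# md5 of the canonical JSON serialisation of the configuration.
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = 12,
                              force = TRUE), tmp)
  tools::md5sum(tmp)
}
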
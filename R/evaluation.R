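#' Blocked cross-validation plan
#'
#' The evaluation design: the series is divided into `n_folds` blocked
#' folds, each a contiguous training window immediately followed by a
#' contiguous test block, with test blocks mutually disjoint and fold
#' placement re-randomised on every repetition. Temporal order is always
#' respected: every training index of a fold strictly precedes every test
#' index of that fold, so no future information leaks into training.
#'
#' @param n_folds Number of folds per repetition.
#' @param train_window_months Length of each training block in months.
#' @param horizons Forecast horizons (months) scored within each test block;
#'   the test block length is `max(horizons)`.
#' @param n_repetitions Number of re-randomised repetitions.
#' @param seed Integer seed; all fold placement and model seeds derive
#'   from it.
#' @return A `cv_plan` list.
#' @export
cv_plan <- function(n_folds = 5L, train_window_months = 15L,
                    horizons = c(1L, 3L, 6L, 12L), n_repetitions = 1000L,
                    seed = 1L) {
  horizons <- sort(unique(as.integer(horizons)))
  if (any(horizons < 1L)) stop("horizons must be positive", call. = FALSE)
  structure(list(n_folds = as.integer(n_folds),
                 train_window_months = as.integer(train_window_months),
                 horizons = horizons,
                 n_repetitions = as.integer(n_repetitions),
                 seed = as.integer(seed)),
            class = "cv_plan")
}

#' Lay out the blocked folds of one repetition
#'
#' Test blocks (length `max(plan$horizons)`) are placed without overlap,
#' each immediately preceded by its training window; the slack left over by
#' the minimal layout is distributed uniformly at random (seeded) over the
#' gaps before, between and after the test blocks. At the exact minimum
#' series length there is a single feasible layout, returned for any seed.
#'
#' @param series_length Number of months available.
#' @param plan A [cv_plan()].
#' @param repetition_seed Seed for this repetition's placement.
#' @return List of folds, each `list(train = , test = )` of integer index
#'   vectors.
#' @export
make_blocked_folds <- function(series_length, plan, repetition_seed = plan$seed) {
  W <- plan$train_window_months
  L <- max(plan$horizons)
  nf <- plan$n_folds
  min_len <- W + nf * L
  if (series_length < min_len) {
    stop(sprintf("insufficient data for the blocked CV plan: %d months given, minimum is train_window + n_folds * max(horizons) = %d + %d*%d = %d",
                 series_length, W, nf, L, min_len), call. = FALSE)
  }
  S <- series_length - min_len
  gaps <- if (S == 0L) {
    rep(0L, nf + 1L)
  } else {
    with_local_seed(repetition_seed, random_composition(S, nf + 1L))
  }
  folds <- vector("list", nf)
  test_start <- W + 1L
  for (i in seq_len(nf)) {
    test_start <- test_start + gaps[i]
    folds[[i]] <- list(train = (test_start - W):(test_start - 1L),
                       test = test_start:(test_start + L - 1L))
    test_start <- test_start + L
  }
  folds
}

# Uniform random composition of S into k non-negative parts
# (stars and bars: k - 1 cut points among S + k - 1 slots).
random_composition <- function(S, k) {
  if (k == 1L) return(S)
  cuts <- sort(sample.int(S + k - 1L, k - 1L))
  diff(c(0L, cuts, S + k)) - 1L
}

#' Median absolute error
#'
#' The median of the absolute forecast errors — robust to the occasional
#' large miss, which is why it scores this evaluation.
#'
#' @param actual,predicted Equal-length numeric vectors.
#' @return Non-negative scalar.
#' @export
median_absolute_error <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    stop("`actual` and `predicted` must have the same length", call. = FALSE)
  }
  if (length(actual) == 0L) stop("empty input", call. = FALSE)
  stats::median(abs(actual - predicted))
}

#' Median absolute percentage error
#'
#' Median of `100 * |actual - predicted| / actual` over the entries with a
#' non-zero actual; zero-actual terms are skipped (their count is reported
#' in a warning), and an all-zero actual vector leaves the metric undefined.
#'
#' @inheritParams median_absolute_error
#' @return Percentage on the 0-100 scale.
#' @export
median_absolute_percentage_error <- function(actual, predicted) {
  out <- mape_impl(actual, predicted)
  if (out$skipped > 0L) {
    warning(sprintf("%d zero-actual term(s) skipped in the percentage error", out$skipped),
            call. = FALSE)
  }
  out$value
}

mape_impl <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    stop("`actual` and `predicted` must have the same length", call. = FALSE)
  }
  keep <- actual != 0
  if (!any(keep)) {
    stop("undefined metric: every actual value is zero", call. = FALSE)
  }
  list(value = stats::median(100 * abs(actual[keep] - predicted[keep]) / abs(actual[keep])),
       skipped = sum(!keep))
}

#' Blocked cross-validation of forecasters
#'
#' For every repetition the folds are re-placed ([make_blocked_folds()]);
#' each model is trained on each fold's training block only and scored on
#' the first `h` test months for every horizon `h` in the plan. The score
#' of a (model, horizon) cell is the median over all repetitions and folds
#' of the fold-level median errors; the reported dispersion is the standard
#' deviation of those fold-level values (on the absolute-error scale).
#' Model failures on a fold are recorded and excluded, never silently
#' dropped; skipped zero-actual percentage terms are counted. All
#' randomness derives from `plan$seed`, and scores do not depend on the
#' order in which models are listed.
#'
#' @param series A [monthly_series()].
#' @param models List of `forecaster_adapter`s (see [builtin_forecasters()]
#'   and [wrap_external_forecaster()]).
#' @param plan A [cv_plan()].
#' @return A `score_table`: data frame with columns `model`,
#'   `horizon_months`, `mae`, `mape_percent`, `sd`, `n_evaluations`,
#'   `n_failures`; fold-level errors are kept in `attr(, "fold_errors")`
#'   for [compare_models()].
#' @export
cross_validate <- function(series, models, plan = cv_plan()) {
  if (inherits(models, "forecaster_adapter")) models <- list(models)
  models <- lapply(models, function(m) {
    if (!inherits(m, "forecaster_adapter")) {
      stop("`models` must be forecaster_adapter objects", call. = FALSE)
    }
    m
  })
  model_names <- vapply(models, function(m) m$name, character(1))
  if (anyDuplicated(model_names)) stop("model names must be unique", call. = FALSE)
  L <- max(plan$horizons)
  n <- nrow(series)
  n_cells <- plan$n_repetitions * plan$n_folds * length(models) * length(plan$horizons)
  col_rep <- integer(n_cells); col_fold <- integer(n_cells)
  col_model <- character(n_cells); col_h <- integer(n_cells)
  col_mae <- numeric(n_cells); col_mape <- numeric(n_cells)
  filled <- 0L
  n_failures <- stats::setNames(integer(length(models)), model_names)
  n_skipped_zero <- 0L
  for (rep_i in seq_len(plan$n_repetitions)) {
    rep_seed <- derive_seed(plan$seed, rep_i)
    folds <- make_blocked_folds(n, plan, rep_seed)
    for (fold_i in seq_along(folds)) {
      fold <- folds[[fold_i]]
      train <- monthly_series(series$month[fold$train], series$count[fold$train])
      actual <- series$count[fold$test]
      for (m in models) {
        fc <- tryCatch(m$fit_and_forecast(train, L, derive_seed(rep_seed, fold_i)),
                       error = function(e) e)
        if (inherits(fc, "error")) {
          n_failures[m$name] <- n_failures[m$name] + 1L
          next
        }
        for (h in plan$horizons) {
          a <- actual[seq_len(h)]
          p <- fc$point[seq_len(h)]
          mape <- tryCatch(mape_impl(a, p), error = function(e) NULL)
          if (!is.null(mape)) n_skipped_zero <- n_skipped_zero + mape$skipped
          filled <- filled + 1L
          col_rep[filled] <- rep_i; col_fold[filled] <- fold_i
          col_model[filled] <- m$name; col_h[filled] <- h
          col_mae[filled] <- median_absolute_error(a, p)
          col_mape[filled] <- if (is.null(mape)) NA_real_ else mape$value
        }
      }
    }
  }
  if (filled == 0L) {
    stop("every model failed on every fold; nothing to score", call. = FALSE)
  }
  keep <- seq_len(filled)
  errors <- data.frame(repetition = col_rep[keep], fold = col_fold[keep],
                       model = col_model[keep], horizon = col_h[keep],
                       mae = col_mae[keep], mape = col_mape[keep],
                       stringsAsFactors = FALSE)
  if (any(n_failures > 0L)) {
    message(sprintf("cross_validate: %d model fit(s) failed and were excluded (%s)",
                    sum(n_failures),
                    paste(sprintf("%s: %d", names(n_failures)[n_failures > 0],
                                  n_failures[n_failures > 0]), collapse = ", ")))
  }
  if (n_skipped_zero > 0L) {
    message(sprintf("cross_validate: %d zero-actual percentage term(s) skipped", n_skipped_zero))
  }
  cells <- expand.grid(model = model_names, horizon_months = plan$horizons,
                       stringsAsFactors = FALSE)
  cells <- cells[order(match(cells$model, sort(model_names)), cells$horizon_months), ]
  score <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- errors$model == cells$model[i] & errors$horizon == cells$horizon_months[i]
    e <- errors[sel, , drop = FALSE]
    data.frame(model = cells$model[i], horizon_months = cells$horizon_months[i],
               mae = stats::median(e$mae),
               mape_percent = stats::median(e$mape, na.rm = TRUE),
               sd = stats::sd(e$mae),
               n_evaluations = nrow(e),
               n_failures = n_failures[[cells$model[i]]])
  }))
  rownames(score) <- NULL
  structure(score, class = c("score_table", "data.frame"),
            fold_errors = errors, plan = plan)
}

#' @export
print.score_table <- function(x, ...) {
  cat("<score_table> blocked cross-validation scores\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a score table as CSV
#' @param table A `score_table`.
#' @param path Output file path.
#' @export
write_scores_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Compare models against baselines
#'
#' For every non-baseline model, horizon and baseline: the ratio of the
#' score-table cell errors, and a paired sign-flip permutation p-value on
#' the fold-level median absolute errors (pairing by repetition and fold;
#' the observed statistic is the mean paired difference, its sign flipped
#' uniformly at random per pair, two-sided).
#'
#' @param table A `score_table` from [cross_validate()].
#' @param baseline_names Names of the baseline models in the table.
#' @param n_permutations Number of sign-flip draws.
#' @param seed Seed for the permutation draws.
#' @return Data frame: model, baseline, horizon_months, mae_ratio,
#'   mape_ratio, p_value.
#' @export
compare_models <- function(table, baseline_names, n_permutations = 10000L,
                           seed = 1L) {
  errors <- attr(table, "fold_errors")
  if (is.null(errors)) stop("`table` must come from cross_validate()", call. = FALSE)
  have <- unique(table$model)
  missing_b <- setdiff(baseline_names, have)
  if (length(missing_b)) {
    stop(sprintf("baseline(s) not in the score table: %s",
                 paste(missing_b, collapse = ", ")), call. = FALSE)
  }
  candidates <- setdiff(have, baseline_names)
  out <- list()
  for (model in sort(candidates)) {
    for (baseline in sort(baseline_names)) {
      for (h in sort(unique(table$horizon_months))) {
        me <- errors[errors$model == model & errors$horizon == h, ]
        be <- errors[errors$model == baseline & errors$horizon == h, ]
        key <- function(e) paste(e$repetition, e$fold)
        common <- intersect(key(me), key(be))
        d <- me$mae[match(common, key(me))] - be$mae[match(common, key(be))]
        p <- sign_flip_p(d, n_permutations, derive_seed(seed, h))
        cell <- function(m, col) table[table$model == m & table$horizon_months == h, col]
        out[[length(out) + 1L]] <- data.frame(
          model = model, baseline = baseline, horizon_months = h,
          mae_ratio = cell(model, "mae") / cell(baseline, "mae"),
          mape_ratio = cell(model, "mape_percent") / cell(baseline, "mape_percent"),
          p_value = p)
      }
    }
  }
  do.call(rbind, out)
}

# Two-sided paired sign-flip permutation p-value for mean(d) = 0.
sign_flip_p <- function(d, n_permutations, seed) {
  d <- d[is.finite(d)]
  n <- length(d)
  if (n == 0L) return(NA_real_)
  obs <- abs(mean(d))
  with_local_seed(seed, {
    hits <- 0L
    for (b in seq_len(n_permutations)) {
      flip <- sample(c(-1, 1), n, replace = TRUE)
      if (abs(mean(flip * d)) >= obs - 1e-12) hits <- hits + 1L
    }
    (hits + 1L) / (n_permutations + 1L)
  })
}

# Deterministic substream seed derivation (kept inside 32-bit range).
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483647)
}
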
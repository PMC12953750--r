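# Metric registry: daily flag-count column and proportion column per metric.
.METRICS <- tibble::tibble(
  metric = c("suicide", "negative", "neg_selfref"),
  count_col = c("n_suicide", "n_negative", "n_neg_selfref"),
  prop_col = c("prop_suicide", "prop_negative", "prop_neg_selfref")
)

.metric_cols <- function(metric) {
  row <- .METRICS[.METRICS$metric == metric, ]
  if (nrow(row) != 1) {
    stop("unknown metric '", metric, "'; available: ",
         paste(.METRICS$metric, collapse = ", "), call. = FALSE)
  }
  row
}

#' Aggregate entry labels into a daily metric series
#'
#' One row per civil day over the full study span (days with no entries are
#' kept with `n_entries = 0` and missing proportions — missing days are never
#' imputed as zero). `day_index` is relative to hospitalization (Day 0 = the
#' hospitalization date).
#'
#' @param record a [participant_record()].
#' @param labels tibble with columns entry_id, suicide_flag, negative,
#'   negative_self_ref covering exactly the record's entries (either
#'   [label_entries()] output or a ground-truth label table).
#' @return tibble of class `daily_metrics` with per-day counts
#'   (n_entries, n_suicide, n_negative, n_neg_selfref) and proportions
#'   (prop_suicide, prop_negative, prop_neg_selfref).
#' @export
daily_metrics <- function(record, labels) {
  stopifnot(inherits(record, "participant_record"))
  need <- c("entry_id", "suicide_flag", "negative", "negative_self_ref")
  miss <- setdiff(need, names(labels))
  if (length(miss)) {
    stop("labels missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!setequal(labels$entry_id, record$entries$entry_id)) {
    stop("labels do not match the record's entries", call. = FALSE)
  }
  df <- record$entries |>
    select("entry_id", "timestamp") |>
    left_join(as_tibble(labels)[, need], by = "entry_id") |>
    mutate(date = civil_date(.data$timestamp))
  per_day <- df |>
    group_by(.data$date) |>
    summarise(n_entries = n(),
              n_suicide = sum(.data$suicide_flag),
              n_negative = sum(.data$negative),
              n_neg_selfref = sum(.data$negative_self_ref),
              .groups = "drop")
  grid <- tibble(date = seq(record$study_start, record$study_end, by = "day"))
  out <- grid |>
    left_join(per_day, by = "date") |>
    mutate(across(c("n_entries", "n_suicide", "n_negative", "n_neg_selfref"),
                  ~ as.integer(tidyr::replace_na(.x, 0L))),
           prop_suicide = ifelse(.data$n_entries > 0,
                                 .data$n_suicide / .data$n_entries, NA_real_),
           prop_negative = ifelse(.data$n_entries > 0,
                                  .data$n_negative / .data$n_entries, NA_real_),
           prop_neg_selfref = ifelse(.data$n_entries > 0,
                                     .data$n_neg_selfref / .data$n_entries,
                                     NA_real_),
           participant_id = record$participant_id,
           day_index = as.integer(.data$date - record$hospitalization_date)) |>
    select("participant_id", "date", "day_index", everything())
  class(out) <- c("daily_metrics", class(out))
  out
}

#' Whole-study mean frequency of a metric
#'
#' The study mean anchors within-person centering and the window ratio. Two
#' estimators are available: `"pooled"` (total flagged entries / total
#' entries — entry-weighted, robust to low-entry days; the default) and
#' `"day_mean"` (unweighted mean of daily proportions over non-missing days).
#' The two differ whenever daily entry counts vary; [pooling_discrepancy()]
#' reports the difference as a diagnostic.
#'
#' @param series a [daily_metrics()] tibble.
#' @param metric one of `"suicide"`, `"negative"`, `"neg_selfref"`.
#' @param method `"pooled"` or `"day_mean"`.
#' @return frequency (numeric scalar).
#' @export
study_mean <- function(series, metric, method = c("pooled", "day_mean")) {
  method <- match.arg(method)
  cols <- .metric_cols(metric)
  total <- sum(series$n_entries)
  if (total == 0) stop("series has zero total entries", call. = FALSE)
  if (method == "pooled") {
    sum(series[[cols$count_col]]) / total
  } else {
    mean(series[[cols$prop_col]], na.rm = TRUE)
  }
}

#' Pooled vs day-averaged frequency discrepancy (diagnostic)
#'
#' @inheritParams study_mean
#' @return named numeric: pooled, day_mean and their difference.
#' @export
pooling_discrepancy <- function(series, metric) {
  p <- study_mean(series, metric, "pooled")
  d <- study_mean(series, metric, "day_mean")
  c(pooled = p, day_mean = d, difference = p - d)
}

#' Center a daily series on the person-specific study mean
#'
#' Each day's proportion minus the whole-study mean frequency for that
#' participant; missing days stay missing. Centering is what lets departures
#' from a person's typical language level be read directly off the panel.
#'
#' @inheritParams study_mean
#' @return tibble (participant_id, date, day_index, n_entries, value,
#'   centered) where `value` is the daily proportion and `centered` is
#'   `value - study_mean`.
#' @export
center_series <- function(series, metric, method = c("pooled", "day_mean")) {
  method <- match.arg(method)
  cols <- .metric_cols(metric)
  mu <- study_mean(series, metric, method)
  tibble(participant_id = series$participant_id,
         date = series$date,
         day_index = series$day_index,
         n_entries = series$n_entries,
         value = series[[cols$prop_col]],
         centered = series[[cols$prop_col]] - mu)
}

#' Split a daily series into acute and baseline period views
#'
#' The acute period spans day indices `-A..0` (ending at Day 0, the
#' hospitalization day) and the baseline spans `-30..-(A+1)`. A participant
#' enrolled fewer than `30` days before Day 0 gets a truncated (possibly
#' empty) baseline rather than an error.
#'
#' @param series a [daily_metrics()] tibble.
#' @param A acute-period length in days before Day 0 (default 10, the
#'   standard acute risk window; the acute view has `A + 1` day-slots because
#'   Day 0 is included).
#' @param baseline_start first day index of the baseline window (default -30).
#' @return list of class `period_split` with `acute` and `baseline` row
#'   subsets of `series` and the `A` used.
#' @export
split_periods <- function(series, A = 10, baseline_start = -30) {
  if (!is_count(A) || A < 1) stop("A must be a positive integer", call. = FALSE)
  acute <- series[series$day_index >= -A & series$day_index <= 0, ]
  baseline <- series[series$day_index >= baseline_start &
                       series$day_index <= -(A + 1), ]
  structure(list(acute = acute, baseline = baseline, A = A),
            class = "period_split")
}

#' Within-person acute-window ratio curve
#'
#' For each window length `w`, the ratio of the pooled flag frequency over
#' the `w` calendar days ending at Day 0 (days `-(w-1)..0`, including the
#' hospitalization day) to the pooled frequency over the entire study. A
#' ratio of 1 means the acute window matches the person's typical level.
#' Windows containing no entries yield `NA`; if the metric is never flagged
#' study-wide the whole curve is undefined (returned as `NA` with a warning,
#' not an error).
#'
#' @inheritParams study_mean
#' @param w_max maximum window length (default 30).
#' @param method frequency estimator, as in [study_mean()].
#' @return tibble of class `window_ratio_curve`: (participant_id, metric, w,
#'   window_frequency, ratio) plus attribute `study_mean_frequency`.
#' @export
window_ratio_curve <- function(series, metric, w_max = 30,
                               method = c("pooled", "day_mean")) {
  method <- match.arg(method)
  cols <- .metric_cols(metric)
  if (sum(series$n_entries) == 0) {
    stop("series has zero total entries", call. = FALSE)
  }
  mu <- study_mean(series, metric, method)
  if (is.na(mu) || mu == 0) {
    warning("zero study-wide frequency for metric '", metric,
            "': ratio curve undefined", call. = FALSE)
  }
  flags <- series[[cols$count_col]]
  props <- series[[cols$prop_col]]
  ratios <- rep(NA_real_, w_max)
  freqs <- rep(NA_real_, w_max)
  for (w in seq_len(w_max)) {
    idx <- series$day_index >= -(w - 1) & series$day_index <= 0
    n_win <- sum(series$n_entries[idx])
    if (n_win == 0) next
    f <- if (method == "pooled") sum(flags[idx]) / n_win
         else mean(props[idx], na.rm = TRUE)
    freqs[w] <- f
    if (!is.na(mu) && mu > 0) ratios[w] <- f / mu
  }
  out <- tibble(participant_id = series$participant_id[1], metric = metric,
                w = seq_len(w_max), window_frequency = freqs, ratio = ratios)
  attr(out, "study_mean_frequency") <- mu
  class(out) <- c("window_ratio_curve", class(out))
  out
}

#' Group-level smoothed ratio curve
#'
#' Pools the (w, ratio) points of two or more participants' curves and fits a
#' locally weighted (tricube, locally linear) regression, returning fitted
#' values on the integer window grid with a pointwise uncertainty band from
#' the fit's standard errors.
#'
#' @param curves a [window_ratio_curve()] tibble or list of them (one metric).
#' @param span loess span (default 0.75).
#' @param level coverage of the pointwise band (default 0.95).
#' @return tibble (w, fit, se, lower, upper).
#' @export
group_smooth <- function(curves, span = 0.75, level = 0.95) {
  if (is.list(curves) && !is.data.frame(curves)) curves <- bind_rows(curves)
  if (length(unique(curves$participant_id)) < 2) {
    stop("group_smooth needs curves from at least 2 participants",
         call. = FALSE)
  }
  pts <- curves[is.finite(curves$ratio), ]
  if (nrow(pts) == 0) stop("all ratios are undefined", call. = FALSE)
  fit <- loess(ratio ~ w, data = pts, span = span, degree = 1,
               family = "gaussian",
               control = stats::loess.control(surface = "direct"))
  grid <- sort(unique(pts$w))
  pr <- predict(fit, newdata = data.frame(w = grid), se = TRUE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  tibble(w = grid, fit = as.numeric(pr$fit), se = as.numeric(pr$se.fit),
         lower = as.numeric(pr$fit - z * pr$se.fit),
         upper = as.numeric(pr$fit + z * pr$se.fit))
}

.DEFAULT_TOD_BINS <- c(0, 6, 12, 18, 24)
.DEFAULT_TOD_LABELS <- c("midnight", "morning", "afternoon", "evening")

#' Daily metrics stratified by time of day
#'
#' Computes [daily_metrics()] within each of four time-of-day bins. The
#' default half-open bins are midnight 00-06, morning 06-12, afternoon 12-18,
#' evening 18-24 local time (the field names these bins but rarely defines
#' them; the edges are configurable). Bins with zero entries on a day are
#' missing for that day.
#'
#' @param record a [participant_record()].
#' @param labels entry labels as in [daily_metrics()].
#' @param bin_edges increasing numeric vector of 5 hour values partitioning
#'   the 24-hour day (first 0, last 24).
#' @param bin_labels labels for the 4 bins.
#' @return tibble: daily metric columns plus a `tod_bin` column.
#' @export
time_of_day_metrics <- function(record, labels,
                                bin_edges = .DEFAULT_TOD_BINS,
                                bin_labels = .DEFAULT_TOD_LABELS) {
  if (length(bin_edges) != 5 || is.unsorted(bin_edges, strictly = TRUE) ||
      bin_edges[1] != 0 || bin_edges[5] != 24) {
    stop("bin_edges must partition the 24-hour day into 4 bins", call. = FALSE)
  }
  stopifnot(length(bin_labels) == 4)
  hours <- as.numeric(format(record$entries$timestamp, "%H", tz = "UTC")) +
    as.numeric(format(record$entries$timestamp, "%M", tz = "UTC")) / 60
  bin <- bin_labels[findInterval(hours, bin_edges, rightmost.closed = TRUE)]
  out <- lapply(bin_labels, function(b) {
    sub <- record$entries[bin == b, ]
    sub_rec <- record
    sub_rec$entries <- sub
    sub_labels <- as_tibble(labels)[labels$entry_id %in% sub$entry_id, ]
    dm <- daily_metrics(sub_rec, sub_labels)
    dm$tod_bin <- b
    dm
  })
  bind_rows(out)
}

#' Pooled frequencies by weekday/weekend and period
#'
#' Partitions study days into weekend (Saturday, Sunday) vs weekday and
#' reports pooled flag frequencies for the acute period, the baseline period
#' and the whole study, per metric.
#'
#' @param series a [daily_metrics()] tibble.
#' @param A acute-period length as in [split_periods()].
#' @param baseline_start as in [split_periods()].
#' @return tibble (partition, period, metric, n_entries, n_flagged,
#'   frequency); `frequency` is `NA` where the cell has no entries.
#' @export
weekday_weekend_metrics <- function(series, A = 10, baseline_start = -30) {
  split <- split_periods(series, A = A, baseline_start = baseline_start)
  periods <- list(acute = split$acute, baseline = split$baseline,
                  study = series)
  rows <- list()
  for (p in names(periods)) {
    s <- periods[[p]]
    wk <- is_weekend(s$date)
    for (part in c("weekend", "weekday")) {
      sub <- s[if (part == "weekend") wk else !wk, ]
      for (m in .METRICS$metric) {
        cols <- .metric_cols(m)
        ne <- sum(sub$n_entries)
        nf <- sum(sub[[cols$count_col]])
        rows[[length(rows) + 1]] <- tibble(
          partition = part, period = p, metric = m,
          n_entries = ne, n_flagged = nf,
          frequency = if (ne > 0) nf / ne else NA_real_)
      }
    }
  }
  bind_rows(rows)
}

#' Fraction of days with at least one entry
#'
#' Keyboard-day coverage over a date window: the share of calendar days in
#' the window on which at least one entry was recorded.
#'
#' @param record a [participant_record()].
#' @param window `Date` vector `c(start, end)`; default the full study span.
#' @return coverage fraction in `[0,1]`.
#' @export
day_coverage <- function(record, window = c(record$study_start,
                                            record$study_end)) {
  stopifnot(inherits(window, "Date"), length(window) == 2)
  if (window[2] < window[1]) stop("empty window", call. = FALSE)
  if (window[1] < record$study_start || window[2] > record$study_end) {
    stop("window must lie within the study span", call. = FALSE)
  }
  days <- seq(window[1], window[2], by = "day")
  present <- unique(civil_date(record$entries$timestamp))
  sum(days %in% present) / length(days)
}
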
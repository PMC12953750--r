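#' Default clinician-annotation category vocabulary
#'
#' Seventeen day-level risk-event categories. The core codes follow the
#' conventions of clinician timeline coding in adolescent STB research
#' (suicidal ideation, self-harm, attempts, sexual experiences, family and
#' interpersonal conflict, supporting others, attention-seeking, academic
#' stressors, violence, substance use, treatment, help-seeking, online
#' victimization, religious language, life events, other); the remaining
#' slot is user-defined.
#'
#' @return character vector of 17 category tokens.
#' @export
default_annotation_vocabulary <- function() {
  c("ACUSYM_SI", "SH", "ATTEMPT", "SEXEXP", "FAMCON", "INTCON", "SUPOTH",
    "ATTSEK", "SCHOOL", "VIOLENCE", "SUBSTANCE", "TREATMENT", "HELPSEEK",
    "ONLINE_VICT", "RELIG", "LIFE_EVENT", "OTHER")
}

#' Load clinician annotation events
#'
#' Reads a CSV or JSONL timeline of day-level events (participant_id, date,
#' category, note). Unknown categories are rejected with the offending row;
#' if `records` is supplied, dates outside the participant's study span are
#' rejected with the row.
#'
#' @param path file path (.csv or .jsonl).
#' @param vocabulary allowed category tokens.
#' @param records optional named list of [participant_record()]s for span
#'   validation.
#' @return tibble (participant_id, date, category, note).
#' @export
load_annotations <- function(path, vocabulary = default_annotation_vocabulary(),
                             records = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    df <- bind_rows(lapply(lines, function(l) as_tibble(jsonlite::fromJSON(l))))
  } else if (ext == "csv") {
    df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
  } else {
    stop("unsupported annotation format: .", ext, call. = FALSE)
  }
  need <- c("participant_id", "date", "category")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("annotations missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"note" %in% names(df)) df$note <- ""
  df$date <- as.Date(df$date)
  bad_cat <- which(!df$category %in% vocabulary)
  if (length(bad_cat)) {
    stop("row ", bad_cat[1], ": unknown category '", df$category[bad_cat[1]],
         "'", call. = FALSE)
  }
  if (!is.null(records)) {
    for (i in seq_len(nrow(df))) {
      r <- records[[df$participant_id[i]]]
      if (!is.null(r) && (df$date[i] < r$study_start || df$date[i] > r$study_end)) {
        stop("row ", i, ": date ", df$date[i],
             " outside study span for participant ", df$participant_id[i],
             call. = FALSE)
      }
    }
  }
  as_tibble(df[, c("participant_id", "date", "category", "note")])
}

#' Write annotation events (round-trips with [load_annotations()])
#'
#' @param events annotation tibble.
#' @param path output path (.csv or .jsonl).
#' @return `path`, invisibly.
#' @export
write_annotations <- function(events, path) {
  df <- as_tibble(events)
  df$date <- as.character(df$date)
  ext <- tolower(tools::file_ext(path))
  if (ext == "jsonl") {
    lines <- vapply(seq_len(nrow(df)), function(i) {
      jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    readr::write_csv(df, path, progress = FALSE)
  }
  invisible(path)
}

#' Days on which a metric is elevated above the study mean
#'
#' A day is an elevation day when its daily proportion reaches
#' `threshold_multiplier` times the whole-study mean frequency and the day
#' has at least `min_entries` entries (the minimum-entries guard keeps
#' single-entry days from registering spurious 1.0 proportions).
#'
#' @inheritParams study_mean
#' @param threshold_multiplier elevation threshold as a multiple of the study
#'   mean (default 2).
#' @param min_entries minimum entries for a day to qualify (default 5).
#' @return `Date` vector (possibly empty). Zero study mean yields an empty
#'   set with a warning.
#' @export
elevation_days <- function(series, metric, threshold_multiplier = 2,
                           min_entries = 5) {
  cols <- .metric_cols(metric)
  mu <- study_mean(series, metric, "pooled")
  if (is.na(mu) || mu == 0) {
    warning("zero study mean for metric '", metric,
            "': no elevation days", call. = FALSE)
    return(as.Date(character()))
  }
  props <- series[[cols$prop_col]]
  keep <- !is.na(props) & props >= threshold_multiplier * mu &
    series$n_entries >= min_entries
  sort(series$date[keep])
}

#' Correspondence between clinician events and NLP elevation days
#'
#' Operationalizes the visual event-vs-signal comparison: an event-day
#' matches when any elevation day lies within `tolerance_days` of it.
#' Reports both directions — the recall-like fraction of event-days matched
#' by the signal and the precision-like fraction of elevation days matched
#' by an event — overall and per category.
#'
#' @param events annotation tibble (one participant).
#' @param series that participant's [daily_metrics()].
#' @param metric metric name.
#' @param category_filter optional character vector restricting events to
#'   these categories.
#' @param tolerance_days day tolerance for a match (default 1).
#' @param threshold_multiplier,min_entries passed to [elevation_days()].
#' @return tibble of class `correspondence_result`: one row per category plus
#'   an `ALL` row, with columns category, metric, n_event_days, matched,
#'   unmatched, recall_like, n_elevation_days, elevation_matched,
#'   precision_like, tolerance_days, threshold_multiplier.
#' @export
correspondence <- function(events, series, metric, category_filter = NULL,
                           tolerance_days = 1, threshold_multiplier = 2,
                           min_entries = 5) {
  stopifnot(is_count(tolerance_days))
  events <- as_tibble(events)
  if (nrow(events) &&
      length(unique(events$participant_id)) == 1 &&
      length(unique(series$participant_id)) == 1 &&
      events$participant_id[1] != series$participant_id[1]) {
    stop("events and series are for different participants", call. = FALSE)
  }
  if (!is.null(category_filter)) {
    events <- events[events$category %in% category_filter, ]
  }
  elev <- elevation_days(series, metric,
                         threshold_multiplier = threshold_multiplier,
                         min_entries = min_entries)
  one <- function(ev_dates, category) {
    ev_dates <- unique(ev_dates)
    n_ev <- length(ev_dates)
    matched <- if (n_ev && length(elev)) {
      vapply(ev_dates, function(d) any(abs(as.integer(elev - d)) <=
                                         tolerance_days), logical(1))
    } else logical(n_ev)
    elev_matched <- if (length(elev) && n_ev) {
      vapply(elev, function(d) any(abs(as.integer(ev_dates - d)) <=
                                     tolerance_days), logical(1))
    } else logical(length(elev))
    tibble(category = category, metric = metric,
           n_event_days = n_ev, matched = sum(matched),
           unmatched = n_ev - sum(matched),
           recall_like = if (n_ev) sum(matched) / n_ev else NA_real_,
           n_elevation_days = length(elev),
           elevation_matched = sum(elev_matched),
           precision_like = if (length(elev)) sum(elev_matched) / length(elev)
                            else NA_real_,
           tolerance_days = tolerance_days,
           threshold_multiplier = threshold_multiplier)
  }
  cats <- sort(unique(events$category))
  out <- bind_rows(
    one(events$date, "ALL"),
    bind_rows(lapply(cats, function(cc) one(events$date[events$category == cc],
                                            cc)))
  )
  class(out) <- c("correspondence_result", class(out))
  out
}
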
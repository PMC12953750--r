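#' A participant's study record
#'
#' Bundles the study span, hospitalization date and the ordered text entries
#' of one participant. Day 0 of the relative timeline is the hospitalization
#' date; "day -k" is k civil days before it. Entries after midnight belong to
#' the new civil date.
#'
#' @param participant_id identifier token.
#' @param study_start,study_end,hospitalization_date `Date`s with
#'   `study_start <= hospitalization_date <= study_end`.
#' @param entries tibble with columns entry_id, participant_id, timestamp
#'   (POSIXct), app_id, text, word_count; must be sorted by timestamp and lie
#'   within the study span.
#' @return object of class `participant_record`.
#' @export
participant_record <- function(participant_id, study_start, study_end,
                               hospitalization_date, entries) {
  stopifnot(inherits(study_start, "Date"), inherits(study_end, "Date"),
            inherits(hospitalization_date, "Date"))
  if (!(study_start <= hospitalization_date && hospitalization_date <= study_end)) {
    stop("require study_start <= hospitalization_date <= study_end",
         call. = FALSE)
  }
  entries <- as_tibble(entries)
  required <- c("entry_id", "participant_id", "timestamp", "app_id", "text",
                "word_count")
  missing_cols <- setdiff(required, names(entries))
  if (length(missing_cols)) {
    stop("entries missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(entries)) {
    if (is.unsorted(entries$timestamp)) {
      stop("entries must be sorted by timestamp", call. = FALSE)
    }
    d <- civil_date(entries$timestamp)
    if (any(d < study_start | d > study_end)) {
      stop("entry timestamps outside the study span", call. = FALSE)
    }
  }
  structure(
    list(participant_id = participant_id, study_start = study_start,
         study_end = study_end, hospitalization_date = hospitalization_date,
         entries = entries),
    class = "participant_record"
  )
}

#' @export
print.participant_record <- function(x, ...) {
  cat(sprintf("<participant_record %s: %s..%s, hospitalization %s, %d entries>\n",
              x$participant_id, x$study_start, x$study_end,
              x$hospitalization_date, nrow(x$entries)))
  invisible(x)
}

#' Segment keyboard input events into text entries
#'
#' Reproduces the logical-division rule used by passive keyboard sensing: a
#' new entry begins when the app changes or when the gap to the previous
#' event exceeds `pause_threshold` seconds. Fragments within an entry are
#' concatenated in time order; the entry timestamp is the first fragment's
#' timestamp; entries whose text is empty (or whitespace only) are dropped.
#'
#' @param events tibble with columns participant_id, timestamp (POSIXct),
#'   app_id, fragment; a single participant, sorted by timestamp.
#' @param pause_threshold gap in seconds that opens a new entry (default 60;
#'   the upstream sensing system's actual pause rule is not public, so this
#'   is a configurable stand-in).
#' @return tibble of entries (entry_id, participant_id, timestamp, app_id,
#'   text, word_count).
#' @export
segment_entries <- function(events, pause_threshold = 60) {
  events <- as_tibble(events)
  stopifnot(all(c("participant_id", "timestamp", "app_id", "fragment") %in%
                  names(events)))
  if (!is.numeric(pause_threshold) || length(pause_threshold) != 1 ||
      is.na(pause_threshold) || pause_threshold < 0) {
    stop("pause_threshold must be a nonnegative number", call. = FALSE)
  }
  if (length(unique(events$participant_id)) > 1) {
    stop("segment_entries expects events from a single participant",
         call. = FALSE)
  }
  if (nrow(events) == 0) {
    return(tibble(entry_id = character(), participant_id = character(),
                  timestamp = as.POSIXct(character(), tz = "UTC"),
                  app_id = character(), text = character(),
                  word_count = integer()))
  }
  if (is.unsorted(events$timestamp)) {
    stop("events must be sorted by timestamp", call. = FALSE)
  }
  n <- nrow(events)
  gap <- c(0, as.numeric(difftime(events$timestamp[-1],
                                  events$timestamp[-n], units = "secs")))
  new_entry <- c(TRUE, (events$app_id[-1] != events$app_id[-n]) |
                   (gap[-1] > pause_threshold))
  grp <- cumsum(new_entry)
  out <- events |>
    mutate(.grp = grp) |>
    group_by(.grp) |>
    summarise(participant_id = first(.data$participant_id),
              timestamp = first(.data$timestamp),
              app_id = first(.data$app_id),
              text = paste0(.data$fragment, collapse = ""),
              .groups = "drop") |>
    filter(nchar(stringr::str_trim(.data$text)) > 0)
  out |>
    mutate(entry_id = sprintf("%s-%06d", .data$participant_id, row_number()),
           word_count = count_words(.data$text)) |>
    select("entry_id", "participant_id", "timestamp", "app_id", "text",
           "word_count")
}

.ENTRY_COLS <- c("entry_id", "participant_id", "timestamp", "app_id", "text")

#' Read text entries into participant records
#'
#' Reads a JSONL (one entry object per line) or CSV entry file and partitions
#' it into one [participant_record()] per participant. Participant metadata
#' (study span, hospitalization date) comes from a YAML/JSON sidecar; without
#' one, spans are inferred from the data and the hospitalization date
#' defaults to the last observed day.
#'
#' @param path entry file path.
#' @param format `"jsonl"` or `"csv"` (default: by extension).
#' @param meta optional path to a YAML/JSON sidecar: a list keyed by
#'   participant_id with fields study_start, study_end, hospitalization_date.
#' @return named list of [participant_record()]s.
#' @export
read_entries <- function(path, format = NULL, meta = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  format <- format %||% tolower(tools::file_ext(path))
  if (!format %in% c("jsonl", "csv")) {
    stop("format must be 'jsonl' or 'csv'", call. = FALSE)
  }
  df <- if (format == "jsonl") .read_entries_jsonl(path) else .read_entries_csv(path)
  meta_list <- if (!is.null(meta)) read_config_file(meta) else NULL
  split_dfs <- split(df, df$participant_id)
  out <- lapply(names(split_dfs), function(pid) {
    e <- as_tibble(split_dfs[[pid]]) |> arrange(.data$timestamp)
    e$word_count <- count_words(e$text)
    m <- meta_list[[pid]]
    d <- civil_date(e$timestamp)
    participant_record(
      pid,
      study_start = if (!is.null(m)) as.Date(m$study_start) else min(d),
      study_end = if (!is.null(m)) as.Date(m$study_end) else max(d),
      hospitalization_date = if (!is.null(m)) as.Date(m$hospitalization_date)
                             else max(d),
      entries = e[, c(.ENTRY_COLS[1:4], "text", "word_count")]
    )
  })
  setNames(out, names(split_dfs))
}

.read_entries_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  rows <- lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) stop("malformed JSON at line ", i,
                                             call. = FALSE))
    miss <- setdiff(.ENTRY_COLS, names(obj))
    if (length(miss)) {
      stop("line ", i, ": missing required field(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    obj[.ENTRY_COLS]
  })
  df <- bind_rows(lapply(rows, as_tibble))
  .parse_entry_timestamps(df, "line")
}

.read_entries_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  miss_cols <- setdiff(.ENTRY_COLS, names(df))
  if (length(miss_cols)) {
    stop("missing required field(s): ", paste(miss_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in .ENTRY_COLS) {
    bad <- which(is.na(df[[col]]) | df[[col]] == "")
    if (col != "text" && length(bad)) {
      stop("missing value for '", col, "' at row ", bad[1], call. = FALSE)
    }
  }
  df$text[is.na(df$text)] <- ""
  .parse_entry_timestamps(df, "row")
}

.parse_entry_timestamps <- function(df, unit) {
  ts <- parse_timestamp(df$timestamp)
  bad <- which(is.na(ts))
  if (length(bad)) {
    stop("malformed timestamp at ", unit, " ", bad[1], ": '",
         df$timestamp[bad[1]], "'", call. = FALSE)
  }
  df$timestamp <- ts
  df
}

#' Write participant records to an entry file (plus metadata sidecar)
#'
#' Timestamps are serialized as ISO-8601 local clock times; `write_entries`
#' followed by [read_entries()] (with the sidecar) is the identity on
#' records.
#'
#' @param records a [participant_record()] or list of them.
#' @param path output entry file.
#' @param format `"jsonl"` or `"csv"` (default: by extension).
#' @param meta optional sidecar path (YAML or JSON by extension).
#' @return `path`, invisibly.
#' @export
write_entries <- function(records, path, format = NULL, meta = NULL) {
  if (inherits(records, "participant_record")) records <- list(records)
  format <- format %||% tolower(tools::file_ext(path))
  if (!format %in% c("jsonl", "csv")) {
    stop("format must be 'jsonl' or 'csv'", call. = FALSE)
  }
  df <- bind_rows(lapply(records, function(r) r$entries))
  df <- df[, .ENTRY_COLS]
  df$timestamp <- format_timestamp(df$timestamp)
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(df)), function(i) {
      jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    readr::write_csv(df, path, progress = FALSE)
  }
  if (!is.null(meta)) {
    m <- lapply(records, function(r) {
      list(study_start = as.character(r$study_start),
           study_end = as.character(r$study_end),
           hospitalization_date = as.character(r$hospitalization_date))
    })
    names(m) <- vapply(records, `[[`, character(1), "participant_id")
    if (tolower(tools::file_ext(meta)) %in% c("yaml", "yml")) {
      yaml::write_yaml(m, meta)
    } else {
      jsonlite::write_json(m, meta, auto_unbox = TRUE, pretty = TRUE)
    }
  }
  invisible(path)
}

#' Default PII redaction rules
#'
#' Regex rules covering email addresses, phone-number shapes and URLs. This
#' is a contract-compatible hook, not a full de-identification system: real
#' deployments chain dedicated tooling here.
#'
#' @return named character vector of regular expressions.
#' @export
default_redaction_patterns <- function() {
  c(EMAIL = "[[:alnum:]._%+-]+@[[:alnum:].-]+\\.[[:alpha:]]{2,}",
    URL = "(https?://|www\\.)[^[:space:]]+",
    PHONE = "(\\+?1[ .-]?)?(\\(\\d{3}\\)|\\d{3})[ .-]?\\d{3}[ .-]?\\d{4}")
}

#' Redact PII-shaped spans from text
#'
#' Each match of each rule is replaced by a bracketed placeholder carrying
#' the rule name (e.g. `[PHONE]`). Idempotent: placeholders do not re-match.
#'
#' @param text character vector.
#' @param patterns named character vector of regexes
#'   (default [default_redaction_patterns()]).
#' @return redacted character vector.
#' @export
redact <- function(text, patterns = default_redaction_patterns()) {
  stopifnot(!is.null(names(patterns)), all(nzchar(names(patterns))))
  for (nm in names(patterns)) {
    text <- stringr::str_replace_all(text, patterns[[nm]],
                                     paste0("[", nm, "]"))
  }
  text
}
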
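#' Seeded topic specification
#'
#' Ten supervised topics, each described by a nonempty seed-word set. Entries
#' are assigned to the most similar topic (or to `OUTLIER` below the
#' threshold). Seed sets need not be disjoint; pairwise overlaps are reported
#' at load because diffuse, overlapping topics are exactly the ones that
#' assign least cleanly.
#'
#' @param topics ordered character vector of topic names (the order breaks
#'   exact similarity ties).
#' @param seed_words named list topic -> nonempty character vector.
#' @param assignment_threshold minimum cosine similarity for a non-OUTLIER
#'   assignment, in `[0,1]`. The default 0.2 is a configurable convention,
#'   not an estimated quantity.
#' @param quiet suppress the seed-overlap report.
#' @return object of class `topic_spec` with a precomputed bag-of-words
#'   embedding over the union seed vocabulary.
#' @export
topic_spec <- function(topics = names(.default_topic_seeds()),
                       seed_words = .default_topic_seeds(),
                       assignment_threshold = 0.2,
                       quiet = FALSE) {
  stopifnot(is.character(topics), length(topics) >= 1,
            !anyDuplicated(topics),
            is_probability(assignment_threshold))
  if (!all(topics %in% names(seed_words))) {
    stop("seed_words must provide a set for every topic", call. = FALSE)
  }
  seed_words <- lapply(seed_words[topics],
                       function(x) unique(stringr::str_to_lower(x)))
  if (any(lengths(seed_words) == 0)) {
    stop("every topic needs a nonempty seed set", call. = FALSE)
  }
  overlaps <- list()
  for (i in seq_along(topics)) {
    for (j in seq_len(i - 1)) {
      ov <- intersect(seed_words[[i]], seed_words[[j]])
      if (length(ov)) {
        overlaps[[length(overlaps) + 1]] <-
          sprintf("%s/%s: %s", topics[j], topics[i], paste(ov, collapse = ", "))
      }
    }
  }
  if (length(overlaps) && !quiet) {
    message("seed-word overlaps between topics:\n  ",
            paste(unlist(overlaps), collapse = "\n  "))
  }
  vocab <- unique(unlist(seed_words))
  centroids <- vapply(seed_words, function(sw) {
    v <- as.numeric(vocab %in% sw)
    v / sqrt(sum(v^2))
  }, numeric(length(vocab)))
  structure(
    list(topics = topics, seed_words = seed_words,
         assignment_threshold = assignment_threshold,
         vocab = vocab, centroids = centroids),
    class = "topic_spec"
  )
}

#' Load a topic spec from YAML or JSON
#'
#' The file provides `topics` (ordered names), `seed_words` (map topic ->
#' tokens) and optionally `assignment_threshold`.
#'
#' @param path file path (.yaml/.yml/.json).
#' @inheritParams topic_spec
#' @return a [topic_spec()].
#' @export
topic_spec_from_file <- function(path, quiet = FALSE) {
  cfg <- read_config_file(path)
  topic_spec(topics = unlist(cfg$topics),
             seed_words = lapply(cfg$seed_words, unlist),
             assignment_threshold = cfg$assignment_threshold %||% 0.2,
             quiet = quiet)
}

#' Assign entries to seeded topics by cosine similarity
#'
#' The default embedder is a term-frequency vector over the union seed
#' vocabulary; similarity is the cosine against each topic's (uniform) seed
#' centroid. The assignment is the argmax topic if the maximum similarity
#' reaches the threshold, else `OUTLIER`; exact ties break by topic order.
#' Text sharing no vocabulary with any seed set (including empty text) is
#' `OUTLIER` with similarity 0.
#'
#' @param text character vector of entry texts.
#' @param spec a [topic_spec()].
#' @param entry_id optional ids carried into the result.
#' @return tibble (entry_id, topic, similarity); `topic != "OUTLIER"` implies
#'   `similarity >= assignment_threshold`.
#' @export
assign_topics <- function(text, spec = topic_spec(quiet = TRUE),
                          entry_id = NULL) {
  stopifnot(inherits(spec, "topic_spec"))
  entry_id <- entry_id %||% as.character(seq_along(text))
  stopifnot(length(entry_id) == length(text))
  tokens <- tokenize_words(text)
  V <- length(spec$vocab)
  X <- vapply(tokens, function(tk) {
    tabulate(match(tk, spec$vocab), nbins = V)
  }, numeric(V))
  X <- matrix(X, nrow = V)
  norms <- sqrt(colSums(X^2))
  sims <- t(spec$centroids) %*% X        # topics x entries
  ok <- norms > 0
  sims[, ok] <- sweep(sims[, ok, drop = FALSE], 2, norms[ok], "/")
  sims[, !ok] <- 0
  best <- apply(sims, 2, which.max)      # first max = topic-order tie-break
  best_sim <- sims[cbind(best, seq_along(text))]
  topic <- ifelse(best_sim >= spec$assignment_threshold & norms > 0,
                  spec$topics[best], "OUTLIER")
  similarity <- ifelse(norms > 0, best_sim, 0)
  tibble(entry_id = entry_id, topic = topic, similarity = similarity)
}

#' Single-entry topic assignment
#'
#' @inheritParams assign_topics
#' @return one-row tibble (entry_id, topic, similarity).
#' @export
assign_topic <- function(text, spec = topic_spec(quiet = TRUE)) {
  stopifnot(length(text) == 1)
  assign_topics(text, spec)
}

#' Daily topic counts and proportions
#'
#' Per civil day: entry count per topic (including `OUTLIER`) and the
#' proportion of that day's entries. Days with zero entries are present with
#' `n_entries = 0` and missing proportions.
#'
#' @param assignments tibble from [assign_topics()], covering the record's
#'   entries.
#' @param record a [participant_record()].
#' @return tibble (participant_id, date, day_index, topic, n_entries, count,
#'   proportion), one row per day x topic level.
#' @export
topic_frequencies <- function(assignments, record) {
  stopifnot(inherits(record, "participant_record"))
  unknown <- setdiff(assignments$entry_id, record$entries$entry_id)
  if (length(unknown)) {
    stop("assignment(s) for unknown entry_id: ", unknown[1], call. = FALSE)
  }
  missing_ids <- setdiff(record$entries$entry_id, assignments$entry_id)
  if (length(missing_ids)) {
    stop("assignments do not cover entry_id: ", missing_ids[1], call. = FALSE)
  }
  topics <- c(setdiff(unique(assignments$topic), "OUTLIER"), "OUTLIER")
  dates <- seq(record$study_start, record$study_end, by = "day")
  df <- record$entries |>
    mutate(date = civil_date(.data$timestamp)) |>
    left_join(assignments, by = "entry_id")
  counts <- df |>
    count(.data$date, .data$topic, name = "count")
  grid <- tidyr::expand_grid(date = dates, topic = topics)
  out <- grid |>
    left_join(counts, by = c("date", "topic")) |>
    mutate(count = tidyr::replace_na(.data$count, 0L))
  day_n <- df |> count(.data$date, name = "n_entries")
  out |>
    left_join(day_n, by = "date") |>
    mutate(n_entries = tidyr::replace_na(.data$n_entries, 0L),
           proportion = ifelse(.data$n_entries > 0,
                               .data$count / .data$n_entries, NA_real_),
           participant_id = record$participant_id,
           day_index = as.integer(.data$date - record$hospitalization_date)) |>
    select("participant_id", "date", "day_index", "topic", "n_entries",
           "count", "proportion")
}
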
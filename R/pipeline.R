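#' Run the full analysis pipeline on a synthetic cohort
#'
#' Chains every stage — simulate, label, assign topics, aggregate to daily
#' metrics, compute window-ratio curves and the group smooth, summarize
#' coverage — and writes tidy CSV outputs plus a JSON run manifest to
#' `out_dir`. Given identical configs (including seeds) the written files
#' are byte-identical across runs.
#'
#' @param configs list of [synthetic_config()]s.
#' @param out_dir output directory (created if needed).
#' @param lexicon a [lexicon_spec()].
#' @param scorer a [sentiment_scorer()].
#' @param tspec a [topic_spec()].
#' @param w_max maximum ratio-curve window length.
#' @return invisibly, a list with the cohort, labels, assignments, daily
#'   series, curves, smooth (or NULL), coverage and the written file paths.
#' @export
run_pipeline <- function(configs, out_dir,
                         lexicon = default_lexicon(),
                         scorer = rule_sentiment_scorer(),
                         tspec = topic_spec(quiet = TRUE),
                         w_max = 30) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(configs)
  records <- lapply(cohort, `[[`, "record")

  write_entries(records, file.path(out_dir, "entries.jsonl"),
                meta = file.path(out_dir, "participants.yaml"))

  labels <- lapply(records, label_entries, lexicon = lexicon, scorer = scorer)
  assignments <- lapply(records, function(r) {
    assign_topics(r$entries$text, tspec, entry_id = r$entries$entry_id)
  })

  labels_flat <- bind_rows(lapply(names(records), function(pid) {
    l <- labels[[pid]]
    tibble(participant_id = pid, entry_id = l$entry_id,
           suicide_flag = l$suicide_flag,
           sentiment_label = l$sentiment_label,
           negative = l$negative, negative_self_ref = l$negative_self_ref,
           topic = assignments[[pid]]$topic,
           similarity = assignments[[pid]]$similarity)
  }))
  readr::write_csv(labels_flat, file.path(out_dir, "labels.csv"),
                   progress = FALSE)

  series <- lapply(names(records), function(pid) {
    daily_metrics(records[[pid]], labels[[pid]])
  })
  names(series) <- names(records)
  daily_long <- bind_rows(lapply(series, function(s) {
    bind_rows(lapply(.METRICS$metric, function(m) {
      cols <- .metric_cols(m)
      tibble(participant_id = s$participant_id, date = s$date,
             day_index = s$day_index, metric = m, n_entries = s$n_entries,
             n_flagged = s[[cols$count_col]], value = s[[cols$prop_col]])
    }))
  }))
  readr::write_csv(daily_long, file.path(out_dir, "daily_metrics.csv"),
                   progress = FALSE)

  curves <- bind_rows(lapply(series, function(s) {
    bind_rows(lapply(.METRICS$metric, function(m) {
      suppressWarnings(window_ratio_curve(s, m, w_max = w_max))
    }))
  }))
  readr::write_csv(curves, file.path(out_dir, "ratio_curves.csv"),
                   progress = FALSE)

  smooth <- NULL
  if (length(records) >= 2) {
    smooth <- bind_rows(lapply(.METRICS$metric, function(m) {
      sub <- curves[curves$metric == m, ]
      if (!any(is.finite(sub$ratio))) return(NULL)
      sm <- group_smooth(sub)
      sm$metric <- m
      sm
    }))
    readr::write_csv(smooth, file.path(out_dir, "group_smooth.csv"),
                     progress = FALSE)
  }

  topic_daily <- bind_rows(lapply(names(records), function(pid) {
    topic_frequencies(assignments[[pid]], records[[pid]])
  }))
  readr::write_csv(topic_daily, file.path(out_dir, "topic_daily.csv"),
                   progress = FALSE)

  coverage <- tibble(
    participant_id = names(records),
    coverage = vapply(records, day_coverage, numeric(1))
  )
  readr::write_csv(coverage, file.path(out_dir, "coverage.csv"),
                   progress = FALSE)

  manifest <- list(
    package = "acutelang",
    version = as.character(utils::packageVersion("acutelang")),
    lexicon = list(name = lexicon$name, version = lexicon$version),
    scorer = list(name = scorer$name, version = scorer$version),
    topic_threshold = tspec$assignment_threshold,
    w_max = w_max,
    participants = lapply(configs, function(cfg) {
      cfg_out <- unclass(cfg)
      cfg_out$study_start <- as.character(cfg_out$study_start)
      cfg_out$topic_mixture <- as.list(cfg_out$topic_mixture)
      cfg_out$diurnal_weights <- as.list(cfg_out$diurnal_weights)
      cfg_out
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  files <- list.files(out_dir, full.names = TRUE)
  invisible(list(cohort = cohort, labels = labels, assignments = assignments,
                 series = series, curves = curves, smooth = smooth,
                 coverage = coverage, files = files))
}
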
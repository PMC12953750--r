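#' Configuration for a synthetic participant stream
#'
#' Defines a single simulated participant: study length, hospitalization day,
#' entry volume, per-entry base rates for suicide-related language and
#' negative sentiment, topic mixture, an acute-period elevation (a step
#' function over the onset window ending on the hospitalization day), day
#' missingness, diurnal structure, and a weekend multiplier for suicide
#' language. Defaults emulate the study conditions this package targets: a
#' 6-month (180-day) observation span with on the order of a hundred entries
#' per day, a negative-sentiment base rate an order of magnitude above the
#' suicide-language base rate, high keyboard-day coverage, and a strong
#' suicide-language elevation confined to the last days before admission.
#'
#' @param participant_id identifier token.
#' @param study_days number of study days (default 180).
#' @param hospitalization_day 1-based day index of hospitalization within the
#'   study (Day 0 of the relative timeline).
#' @param study_start first civil date of the study.
#' @param entries_per_day_mean,entries_per_day_dispersion mean and dispersion
#'   (negative-binomial size) of the daily entry count; non-missing days are
#'   guaranteed at least one entry.
#' @param base_rate_suicide,base_rate_negative per-entry probabilities outside
#'   the elevation window.
#' @param base_rate_neg_selfref_given_negative probability that a negative
#'   entry is also self-referential.
#' @param topic_mixture named numeric vector of per-entry topic probabilities
#'   (sum <= 1; remainder is no-topic text).
#' @param elevation_suicide,elevation_negative multiplicative elevations
#'   applied on days `[hospitalization_day - elevation_onset_days_before,
#'   hospitalization_day]`; elevated probabilities are clipped at 1.
#' @param elevation_onset_days_before length of the onset window before Day 0
#'   (>= 1; the window itself spans `elevation_onset_days_before + 1` days
#'   because Day 0 is included).
#' @param missing_day_prob probability a study day records no entries.
#' @param diurnal_weights nonnegative weights for the four time-of-day bins,
#'   named morning/afternoon/evening/midnight.
#' @param weekend_multiplier_suicide multiplier on the per-entry suicide
#'   probability on Saturdays and Sundays.
#' @param rng_seed integer seed; identical configs generate byte-identical
#'   streams.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(participant_id = "SYN01",
                             study_days = 180L,
                             hospitalization_day = 150L,
                             study_start = as.Date("2023-01-02"),
                             entries_per_day_mean = 120,
                             entries_per_day_dispersion = 10,
                             base_rate_suicide = 0.02,
                             base_rate_negative = 0.30,
                             base_rate_neg_selfref_given_negative = 0.5,
                             topic_mixture = setNames(rep(0.06, 10),
                                                      names(.default_topic_seeds())),
                             elevation_suicide = 5,
                             elevation_negative = 2,
                             elevation_onset_days_before = 5L,
                             missing_day_prob = 0.036,
                             diurnal_weights = c(morning = 0.25, afternoon = 0.35,
                                                 evening = 0.30, midnight = 0.10),
                             weekend_multiplier_suicide = 1,
                             rng_seed = 1L) {
  stopifnot(is.character(participant_id), nchar(participant_id) > 0,
            is_count(study_days), study_days >= 1,
            is_count(hospitalization_day),
            inherits(study_start, "Date"),
            is.numeric(entries_per_day_mean), entries_per_day_mean > 0,
            is.numeric(entries_per_day_dispersion), entries_per_day_dispersion > 0,
            is_probability(base_rate_suicide),
            is_probability(base_rate_negative),
            is_probability(base_rate_neg_selfref_given_negative),
            is_probability(missing_day_prob),
            is.numeric(elevation_suicide), elevation_suicide >= 0,
            is.numeric(elevation_negative), elevation_negative >= 0,
            is_count(elevation_onset_days_before), elevation_onset_days_before >= 1,
            is.numeric(weekend_multiplier_suicide), weekend_multiplier_suicide >= 0,
            is_count(rng_seed))
  if (hospitalization_day < 1 || hospitalization_day > study_days) {
    stop("hospitalization_day must lie within the study span", call. = FALSE)
  }
  if (hospitalization_day - elevation_onset_days_before < 1) {
    stop("elevation window extends before study start", call. = FALSE)
  }
  if (is.null(names(topic_mixture)) || any(names(topic_mixture) == "")) {
    stop("topic_mixture must be a named vector", call. = FALSE)
  }
  if (any(topic_mixture < 0) || sum(topic_mixture) > 1 + 1e-12) {
    stop("topic_mixture must be nonnegative and sum to <= 1", call. = FALSE)
  }
  if (length(diurnal_weights) != 4 || any(diurnal_weights < 0) ||
      sum(diurnal_weights) <= 0) {
    stop("diurnal_weights must be 4 nonnegative reals with positive sum",
         call. = FALSE)
  }
  structure(
    list(participant_id = participant_id,
         study_days = as.integer(study_days),
         hospitalization_day = as.integer(hospitalization_day),
         study_start = study_start,
         entries_per_day_mean = entries_per_day_mean,
         entries_per_day_dispersion = entries_per_day_dispersion,
         base_rate_suicide = base_rate_suicide,
         base_rate_negative = base_rate_negative,
         base_rate_neg_selfref_given_negative = base_rate_neg_selfref_given_negative,
         topic_mixture = topic_mixture,
         elevation_suicide = elevation_suicide,
         elevation_negative = elevation_negative,
         elevation_onset_days_before = as.integer(elevation_onset_days_before),
         missing_day_prob = missing_day_prob,
         diurnal_weights = diurnal_weights,
         weekend_multiplier_suicide = weekend_multiplier_suicide,
         rng_seed = as.integer(rng_seed)),
    class = "synthetic_config"
  )
}

.TOD_BIN_START <- c(morning = 6, afternoon = 12, evening = 18, midnight = 0)

#' Generate one synthetic participant with ground truth
#'
#' Draws daily entry counts from a zero-truncated negative-binomial law,
#' places timestamps by the four-bin diurnal weights (uniform within bin),
#' draws per-entry truth labels from the configured rates (with the acute
#' elevation applied as a step over the onset window), and assembles entry
#' text from labeled template pools so the default labelers recover the truth
#' exactly.
#'
#' @param config a [synthetic_config()].
#' @return list with `record` (a [participant_record()]) and `truth` (class
#'   `ground_truth`: per-entry labels, per-day true rates, and the elevation
#'   window dates).
#' @export
generate_participant <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$rng_seed)
  D <- config$study_days
  dates <- config$study_start + 0:(D - 1)
  hosp_date <- config$study_start + config$hospitalization_day - 1
  elev_lo <- config$hospitalization_day - config$elevation_onset_days_before
  elevated <- seq_len(D) >= elev_lo & seq_len(D) <= config$hospitalization_day

  missing <- runif(D) < config$missing_day_prob
  counts <- pmax(rnbinom(D, size = config$entries_per_day_dispersion,
                         mu = config$entries_per_day_mean), 1L)
  counts[missing] <- 0L

  p_sui_day <- pmin(1, config$base_rate_suicide *
                      ifelse(elevated, config$elevation_suicide, 1) *
                      ifelse(is_weekend(dates), config$weekend_multiplier_suicide, 1))
  p_neg_day <- pmin(1, config$base_rate_negative *
                      ifelse(elevated, config$elevation_negative, 1))

  day_of <- rep.int(seq_len(D), counts)
  n <- length(day_of)

  w <- config$diurnal_weights / sum(config$diurnal_weights)
  bin <- sample.int(4L, n, replace = TRUE, prob = w)
  bin_start <- unname(.TOD_BIN_START[names(config$diurnal_weights)])
  secs <- (bin_start[bin] + 6 * runif(n)) * 3600
  ts <- as.POSIXct(dates[day_of], tz = "UTC") + secs

  suicide <- runif(n) < p_sui_day[day_of]
  negative <- runif(n) < p_neg_day[day_of]
  self_ref <- negative & (runif(n) < config$base_rate_neg_selfref_given_negative)
  topic_names <- names(config$topic_mixture)
  topic <- sample(c(topic_names, "OUTLIER"), n, replace = TRUE,
                  prob = c(config$topic_mixture, 1 - sum(config$topic_mixture)))
  app <- sample(c("messages", "search", "social", "notes"), n, replace = TRUE,
                prob = c(0.6, 0.15, 0.15, 0.1))

  ord <- order(ts)
  day_of <- day_of[ord]; ts <- ts[ord]; suicide <- suicide[ord]
  negative <- negative[ord]; self_ref <- self_ref[ord]
  topic <- topic[ord]; app <- app[ord]

  pools <- template_pools()
  text <- compose_entry_texts(topic, negative, self_ref, suicide, pools)
  entry_id <- sprintf("%s-%06d", config$participant_id, seq_len(n))

  entries <- tibble(
    entry_id = entry_id,
    participant_id = config$participant_id,
    timestamp = ts,
    app_id = app,
    text = text,
    word_count = count_words(text)
  )
  record <- participant_record(config$participant_id,
                               study_start = config$study_start,
                               study_end = dates[D],
                               hospitalization_date = hosp_date,
                               entries = entries)
  truth_labels <- tibble(
    entry_id = entry_id,
    date = dates[day_of],
    suicide_flag = suicide,
    negative = negative,
    self_ref = self_ref,
    negative_self_ref = negative & self_ref,
    topic = topic
  )
  day_rates <- tibble(
    date = dates,
    day_index = seq_len(D) - config$hospitalization_day,
    missing = missing,
    p_suicide = p_sui_day,
    p_negative = p_neg_day
  )
  truth <- structure(
    list(labels = truth_labels, day_rates = day_rates,
         elevation_window = c(dates[elev_lo], hosp_date),
         config = config),
    class = "ground_truth"
  )
  list(record = record, truth = truth)
}

#' Generate a cohort of synthetic participants
#'
#' @param configs list of [synthetic_config()] with distinct participant ids.
#' @return named list (by participant id) of `list(record, truth)`.
#' @export
generate_cohort <- function(configs) {
  stopifnot(is.list(configs),
            all(vapply(configs, inherits, TRUE, "synthetic_config")))
  ids <- vapply(configs, `[[`, character(1), "participant_id")
  if (anyDuplicated(ids)) {
    stop("duplicate participant_id in cohort configs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  setNames(lapply(configs, generate_participant), ids)
}

#' Closed-form expected window ratio under a step elevation
#'
#' For a homogeneous stream with a step elevation over the onset window, the
#' expected pooled frequency ratio for a `w`-day acute window (ending on the
#' hospitalization day) follows from the mixing proportions of elevated and
#' baseline days, assuming all days present with equal expected entry counts.
#' Used as the analytic oracle for elevation-recovery checks.
#'
#' @param config a [synthetic_config()].
#' @param w acute window length in days (including Day 0).
#' @param metric `"suicide"` or `"negative"`.
#' @return expected ratio (numeric scalar).
#' @export
expected_window_ratio <- function(config, w, metric = c("suicide", "negative")) {
  metric <- match.arg(metric)
  base <- switch(metric, suicide = config$base_rate_suicide,
                 negative = config$base_rate_negative)
  elev <- switch(metric, suicide = config$elevation_suicide,
                 negative = config$elevation_negative)
  p_e <- min(1, base * elev)
  n_elev <- config$elevation_onset_days_before + 1
  e_w <- min(w, n_elev)
  window_mean <- (e_w * p_e + (w - e_w) * base) / w
  study_mean <- (n_elev * p_e + (config$study_days - n_elev) * base) /
    config$study_days
  window_mean / study_mean
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth: %d entries, elevation %s..%s>\n",
              nrow(x$labels), x$elevation_window[1], x$elevation_window[2]))
  invisible(x)
}
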
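# Shared five-case synthetic cohort definition, sourced by the numbered
# analysis scripts. The cohort emulates a six-month passive-sensing study in
# which five adolescents were hospitalized for a suicidal crisis while
# enrolled: per-case entry volumes span the tens-to-hundreds-per-day range,
# one case (C4) shows no acute elevation, and one case (C5) enrolled only ten
# days before hospitalization and so has no baseline period.

library(acutelang)

cohort_configs <- function() {
  mk <- function(id, mean_entries, hosp_day, study_days, elev_sui, elev_neg,
                 seed) {
    synthetic_config(
      participant_id = id,
      study_days = study_days,
      hospitalization_day = hosp_day,
      study_start = as.Date("2023-01-02"),
      entries_per_day_mean = mean_entries,
      entries_per_day_dispersion = 8,
      base_rate_suicide = 0.02,
      base_rate_negative = 0.30,
      elevation_suicide = elev_sui,
      elevation_negative = elev_neg,
      # a step elevation over the final five calendar days (Day -4..0)
      elevation_onset_days_before = 4,
      missing_day_prob = 0.036,
      weekend_multiplier_suicide = 1.5,
      rng_seed = seed
    )
  }
  list(
    mk("C1", 111, 150, 180, 5, 2, 101),
    mk("C2", 145, 150, 180, 5, 2, 102),
    mk("C3", 213, 150, 180, 11, 2, 103),  # sharpest spike of the cohort
    mk("C4", 208, 150, 180, 1, 1, 104),   # the non-elevated case
    mk("C5", 83, 11, 180, 5, 2, 105)      # enrolled 10 days before admission
  )
}

results_dir <- function(...) {
  d <- file.path("results", ...)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}
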
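#!/usr/bin/env Rscript
# Clinician-timeline correspondence: build synthetic day-level annotation
# timelines for the two illustration cases (events planted on truth-elevated
# days plus background events elsewhere), then quantify how NLP elevation
# days line up with them at several tolerances.

source("analysis/00_cohort_config.R")
suppressPackageStartupMessages(library(dplyr))

configs <- cohort_configs()
names(configs) <- vapply(configs, `[[`, character(1), "participant_id")
cohort <- generate_cohort(configs[c("C3", "C4")])

records <- lapply(cohort, `[[`, "record")
labels_flat <- readr::read_csv("results/pipeline/labels.csv",
                               show_col_types = FALSE)

set.seed(2026)
events <- bind_rows(lapply(names(cohort), function(pid) {
  g <- cohort[[pid]]
  win <- seq(g$truth$elevation_window[1], g$truth$elevation_window[2],
             by = "day")
  background <- sample(seq(g$record$study_start + 30,
                           g$record$hospitalization_date - 15, by = "day"), 3)
  tibble(
    participant_id = pid,
    date = c(win[c(1, length(win))], background),
    category = c("ACUSYM_SI", "ATTEMPT", "FAMCON", "SCHOOL", "SUBSTANCE"),
    note = "synthetic timeline event")
}))
ann_path <- file.path(results_dir(), "annotations_synthetic.csv")
write_annotations(events, ann_path)
events <- load_annotations(ann_path, records = records)

res <- bind_rows(lapply(names(cohort), function(pid) {
  lab <- labels_flat[labels_flat$participant_id == pid, ]
  s <- daily_metrics(records[[pid]], lab)
  bind_rows(lapply(c(0, 1, 2), function(tol) {
    r <- correspondence(events[events$participant_id == pid, ], s, "suicide",
                        tolerance_days = tol)
    r$participant_id <- pid
    r
  }))
}))
readr::write_csv(res, file.path(results_dir(), "correspondence.csv"))

overall <- res |> filter(category == "ALL") |>
  select(participant_id, tolerance_days, recall_like, precision_like)
print(as.data.frame(overall), digits = 3)
message("For the elevated case the suicide-language signal recovers the ",
        "timeline events near hospitalization; background events far from ",
        "the crisis remain unmatched, and fractions grow with tolerance.")
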
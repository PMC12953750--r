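#!/usr/bin/env Rscript
# Simulate the five-case cohort and run the full pipeline (segment-ready
# entries -> labels -> topics -> daily metrics -> ratio curves), writing all
# tidy outputs under results/pipeline/. Also writes a per-case data summary
# in the shape study reports use: total entries, mean entries/day over the
# last 30 and 10 days, days with entries, and mean words per entry.

source("analysis/00_cohort_config.R")
suppressPackageStartupMessages(library(dplyr))

configs <- cohort_configs()
out_dir <- results_dir("pipeline")
message("Simulating 5 cases and running the pipeline into ", out_dir, " ...")
run <- run_pipeline(configs, out_dir)

summary_tbl <- bind_rows(lapply(run$cohort, function(g) {
  rec <- g$record
  d <- as.Date(rec$entries$timestamp, tz = "UTC")
  idx <- as.integer(d - rec$hospitalization_date)
  tibble(
    case = rec$participant_id,
    total_entries = nrow(rec$entries),
    entries_per_day_30d = sum(idx >= -29 & idx <= 0) / 30,
    entries_per_day_10d = sum(idx >= -9 & idx <= 0) / 10,
    days_with_entries = length(unique(d)),
    mean_words_per_entry = mean(rec$entries$word_count),
    day_coverage = day_coverage(rec)
  )
}))
readr::write_csv(summary_tbl, file.path("results", "cohort_summary.csv"))
message("Per-case language data summary:")
print(as.data.frame(summary_tbl), digits = 3)
message("Entry volumes span tens to hundreds per day; keyboard-day coverage ",
        sprintf("averages %.1f%%.", 100 * mean(summary_tbl$day_coverage)))
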
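#!/usr/bin/env Rscript
# Render the four figure types: per-case centered panels, group ratio curves
# with loess smooth, topic trajectories for two cases, and the timeline
# heatmap for the annotated case.

source("analysis/00_cohort_config.R")
suppressPackageStartupMessages(library(dplyr))

fig_dir <- results_dir("figures")
records <- read_entries("results/pipeline/entries.jsonl",
                        meta = "results/pipeline/participants.yaml")
labels_flat <- readr::read_csv("results/pipeline/labels.csv",
                               show_col_types = FALSE)
curves <- readr::read_csv("results/pipeline/ratio_curves.csv",
                          show_col_types = FALSE)
topic_daily <- readr::read_csv("results/pipeline/topic_daily.csv",
                               show_col_types = FALSE)

series <- lapply(names(records), function(pid) {
  daily_metrics(records[[pid]],
                labels_flat[labels_flat$participant_id == pid, ])
})
names(series) <- names(records)

for (pid in names(series)) {
  for (m in c("suicide", "negative")) {
    render_case_panel(series[[pid]], m,
                      file = file.path(fig_dir,
                                       sprintf("case_panel_%s_%s.pdf", pid, m)))
  }
}
for (m in c("suicide", "negative")) {
  render_ratio_curves(curves[curves$metric == m, ],
                      file = file.path(fig_dir,
                                       sprintf("ratio_curves_%s.pdf", m)))
}
sel <- c("sex", "sleep", "school", "death", "substance_use", "treatment",
         "eating")
for (pid in c("C2", "C4")) {
  render_topic_trajectories(topic_daily[topic_daily$participant_id == pid, ],
                            sel,
                            file = file.path(fig_dir,
                                             sprintf("topics_%s.pdf", pid)))
}
ann_path <- "results/annotations_synthetic.csv"
if (file.exists(ann_path)) {
  events <- load_annotations(ann_path)
  render_timeline_heatmap(events[events$participant_id == "C3", ],
                          series$C3,
                          file = file.path(fig_dir, "timeline_heatmap_C3.pdf"))
}
message("Wrote ", length(list.files(fig_dir)), " figures to ", fig_dir)
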
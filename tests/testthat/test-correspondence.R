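make_elevated_case <- function(seed = 61, pid = "CR1") {
  cfg <- null_config(seed = seed, pid = pid, days = 60, mean = 80,
                     elevation_suicide = 5, elevation_onset_days_before = 4)
  g <- generate_participant(cfg)
  s <- daily_metrics(g$record, g$truth$labels)
  list(g = g, s = s, cfg = cfg)
}

test_that("annotation files validate categories, spans and round-trip", {
  vocab <- default_annotation_vocabulary()
  expect_length(vocab, 17)
  ev <- tibble::tibble(
    participant_id = "CR1",
    date = as.Date("2023-02-01") + 0:9,
    category = rep(c("ACUSYM_SI", "FAMCON"), 5),
    note = paste("note", 1:10))
  for (ext in c(".csv", ".jsonl")) {
    path <- withr::local_tempfile(fileext = ext)
    write_annotations(ev, path)
    back <- load_annotations(path)
    expect_equal(nrow(back), 10)
    expect_equal(back$date, ev$date)
    expect_identical(back$category, ev$category)
  }
  bad <- ev; bad$category[3] <- "XYZ"
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotations(bad, path)
  expect_error(load_annotations(path), "row 3.*XYZ")
  # date outside the participant's study span
  case <- make_elevated_case()
  out_of_span <- ev; out_of_span$date[5] <- as.Date("2025-01-01")
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_annotations(out_of_span, path2)
  expect_error(load_annotations(path2, records = list(CR1 = case$g$record)),
               "row 5.*outside study span")
})

test_that("elevation days require both the multiplier and the entry minimum", {
  case <- make_elevated_case()
  s <- case$s
  # constant series -> no elevation days at multiplier 2
  const <- s
  const$n_suicide <- as.integer(round(const$n_entries * 0.1))
  const$prop_suicide <- ifelse(const$n_entries > 0,
                               const$n_suicide / const$n_entries, NA_real_)
  expect_length(elevation_days(const, "suicide", 2), 0)
  # a single day at 10x the mean is found
  spike <- const
  i <- 10
  spike$n_suicide[i] <- as.integer(spike$n_entries[i])  # proportion 1
  spike$prop_suicide[i] <- 1
  got <- elevation_days(spike, "suicide", 2)
  expect_true(spike$date[i] %in% got)
  # the min-entries guard drops low-entry days
  tiny <- spike
  tiny$n_entries[i] <- 2L
  tiny$n_suicide[i] <- 2L
  tiny$prop_suicide[i] <- 1
  expect_false(tiny$date[i] %in% elevation_days(tiny, "suicide", 2,
                                                min_entries = 5))
  # zero study mean warns and returns empty
  zero <- s; zero$n_suicide[] <- 0L; zero$prop_suicide[] <- 0
  expect_warning(e0 <- elevation_days(zero, "suicide"), "zero study mean")
  expect_length(e0, 0)
})

test_that("elevation days concentrate inside the injected window", {
  case <- make_elevated_case(seed = 62)
  elev <- elevation_days(case$s, "suicide", threshold_multiplier = 2)
  win <- seq(case$g$truth$elevation_window[1], case$g$truth$elevation_window[2],
             by = "day")
  expect_gte(sum(elev %in% win), 3)         # most of the 5 injected days found
  expect_lte(sum(!elev %in% win), 3)        # few false-positive days
})

test_that("correspondence matches events to elevations with tolerance both ways", {
  case <- make_elevated_case(seed = 63)
  elev <- elevation_days(case$s, "suicide", 2)
  ev_on <- tibble::tibble(participant_id = "CR1", date = elev[1],
                          category = "ACUSYM_SI", note = "")
  res0 <- correspondence(ev_on, case$s, "suicide", tolerance_days = 0)
  expect_equal(res0$recall_like[res0$category == "ALL"], 1)
  # an event two days from the nearest elevation is unmatched at tolerance 1
  far_date <- case$s$date[which.min(abs(as.integer(case$s$date - (min(elev) - 10))))]
  ev_far <- tibble::tibble(participant_id = "CR1", date = far_date,
                           category = "FAMCON", note = "")
  res_far <- correspondence(ev_far, case$s, "suicide", tolerance_days = 1)
  expect_equal(res_far$matched[res_far$category == "ALL"], 0)
  # matched + unmatched = total event-days, fractions in [0,1]
  both <- dplyr::bind_rows(ev_on, ev_far)
  res <- correspondence(both, case$s, "suicide", tolerance_days = 1)
  expect_equal(res$matched + res$unmatched, res$n_event_days)
  expect_true(all(res$recall_like >= 0 & res$recall_like <= 1, na.rm = TRUE))
  # category filter and empty category behave
  res_cat <- correspondence(both, case$s, "suicide",
                            category_filter = "SCHOOL")
  expect_equal(res_cat$n_event_days[res_cat$category == "ALL"], 0)
})

test_that("correspondence fractions are monotone in tolerance and threshold", {
  case <- make_elevated_case(seed = 64)
  set.seed(1)
  ev <- tibble::tibble(
    participant_id = "CR1",
    date = sample(case$s$date, 8),
    category = "OTHER", note = "")
  recalls <- vapply(c(0, 1, 2, 4), function(tol) {
    r <- correspondence(ev, case$s, "suicide", tolerance_days = tol)
    r$recall_like[r$category == "ALL"]
  }, numeric(1))
  expect_true(all(diff(recalls) >= 0))
  recalls_thr <- vapply(c(1.5, 2, 3, 5), function(thr) {
    r <- correspondence(ev, case$s, "suicide", threshold_multiplier = thr)
    r$recall_like[r$category == "ALL"]
  }, numeric(1))
  expect_true(all(diff(recalls_thr) <= 0))
})

test_that("figure renderers produce files for every figure type", {
  case <- make_elevated_case(seed = 65)
  g <- case$g; s <- case$s
  asg <- assign_topics(g$record$entries$text,
                       entry_id = g$record$entries$entry_id)
  freqs <- topic_frequencies(asg, g$record)
  ev <- tibble::tibble(participant_id = "CR1",
                       date = g$record$hospitalization_date - c(0, 2, 5),
                       category = c("ACUSYM_SI", "FAMCON", "SCHOOL"),
                       note = "")
  curves <- dplyr::bind_rows(
    window_ratio_curve(s, "suicide"),
    {
      s2 <- make_elevated_case(seed = 66, pid = "CR2")$s
      window_ratio_curve(s2, "suicide")
    })
  files <- vapply(1:4, function(i) tempfile(fileext = ".pdf"), character(1))
  withr::defer(unlink(files))
  p1 <- render_case_panel(s, "suicide", file = files[1])
  p2 <- render_ratio_curves(curves, file = files[2])
  p3 <- render_topic_trajectories(freqs, c("school", "sleep"), file = files[3])
  p4 <- render_timeline_heatmap(ev, s, file = files[4])
  for (f in files) expect_gt(file.info(f)$size, 0)
  expect_s3_class(p1, "ggplot")
  # one facet per selected topic
  expect_equal(length(unique(ggplot2::ggplot_build(p3)$layout$layout$PANEL)), 2)
  # a case with no baseline history renders acute-only without error
  g5 <- generate_participant(
    synthetic_config(participant_id = "NB", study_days = 11,
                     hospitalization_day = 11, entries_per_day_mean = 30,
                     elevation_onset_days_before = 5, missing_day_prob = 0,
                     rng_seed = 9))
  s5 <- daily_metrics(g5$record, g5$truth$labels)
  expect_s3_class(render_case_panel(s5, "suicide"), "ggplot")
  expect_error(render_case_panel(dplyr::mutate(s5, n_entries = 0L), "suicide"),
               "empty|zero")
})

test_that("the pipeline driver writes the declared outputs deterministically", {
  cfgs <- lapply(1:2, function(i) null_config(seed = 400 + i,
                                              pid = sprintf("PL%d", i),
                                              days = 15, mean = 15))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- run_pipeline(cfgs, d1)
  r2 <- run_pipeline(cfgs, d2)
  expect_true(all(c("entries.jsonl", "labels.csv", "daily_metrics.csv",
                    "ratio_curves.csv", "topic_daily.csv", "coverage.csv",
                    "manifest.json") %in% basename(r1$files)))
  for (f in basename(r1$files)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("checksum of", f))
  }
})
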
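# A tiny hand-built record: 3 days, known flag pattern, one missing day.
make_toy_series <- function() {
  ts <- as.POSIXct(c("2023-06-01 09:00:00", "2023-06-01 10:00:00",
                     "2023-06-01 11:00:00", "2023-06-03 22:00:00",
                     "2023-06-03 23:30:00"), tz = "UTC")
  entries <- tibble::tibble(
    entry_id = paste0("t-", 1:5), participant_id = "TOY",
    timestamp = ts, app_id = "m",
    text = c("kms", "fine", "fine", "i hate this", "fine"),
    word_count = c(1L, 1L, 1L, 3L, 1L))
  rec <- participant_record("TOY", as.Date("2023-06-01"), as.Date("2023-06-03"),
                            as.Date("2023-06-03"), entries)
  list(rec = rec, labels = label_entries(rec))
}

test_that("daily metrics pool flags per civil day and keep missing days missing", {
  toy <- make_toy_series()
  s <- daily_metrics(toy$rec, toy$labels)
  expect_equal(nrow(s), 3)
  expect_equal(s$n_entries, c(3L, 0L, 2L))
  expect_equal(s$prop_suicide, c(1 / 3, NA, 0))
  expect_equal(s$prop_negative, c(0, NA, 1 / 2))
  expect_equal(s$prop_neg_selfref, c(0, NA, 1 / 2))
  expect_equal(s$day_index, c(-2L, -1L, 0L))
  # groupby-date oracle on a generated record
  g <- generate_participant(null_config(seed = 23, pid = "DM1", days = 30,
                                        mean = 40))
  tr <- g$truth$labels
  s2 <- daily_metrics(g$record, tr)
  oracle <- tapply(tr$suicide_flag, tr$date, mean)
  expect_equal(unname(s2$prop_suicide[match(names(oracle), as.character(s2$date))]),
               unname(as.numeric(oracle)))
  expect_error(daily_metrics(g$record, tr[-1, ]), "do not match")
})

test_that("study mean is entry-weighted pooling; day-mean alternative differs as diagnosed", {
  toy <- make_toy_series()
  s <- daily_metrics(toy$rec, toy$labels)
  # pooled: 1 flag / 5 entries
  expect_equal(study_mean(s, "suicide"), 1 / 5)
  # day-mean: mean(1/3, 0)
  expect_equal(study_mean(s, "suicide", "day_mean"), mean(c(1 / 3, 0)))
  d <- pooling_discrepancy(s, "suicide")
  expect_equal(unname(d["difference"]), 1 / 5 - 1 / 6)
  # spec arithmetic: (10 entries, 1 flag) + (90 entries, 0 flags) -> 0.01
  big <- s
  big$n_entries <- c(10L, 0L, 90L)
  big$n_suicide <- c(1L, 0L, 0L)
  expect_equal(study_mean(big, "suicide"), 0.01)
  empty <- s; empty$n_entries[] <- 0L
  expect_error(study_mean(empty, "suicide"), "zero total entries")
})

test_that("centering zeroes the entry-weighted mean and is idempotent", {
  g <- generate_participant(null_config(seed = 41, pid = "C2", days = 40,
                                        mean = 60))
  s <- daily_metrics(g$record, g$truth$labels)
  cs <- center_series(s, "negative")
  ok <- !is.na(cs$centered)
  expect_equal(sum(cs$centered[ok] * cs$n_entries[ok]) / sum(cs$n_entries[ok]),
               0, tolerance = 1e-12)
  # constant series centers to all zeros
  const <- s
  const$n_negative <- as.integer(round(const$n_entries * 0.5))
  const$prop_negative <- ifelse(const$n_entries > 0, 0.5, NA)
  # force exactly representable halves
  const$n_entries <- const$n_entries - const$n_entries %% 2L
  const$n_negative <- const$n_entries %/% 2L
  const$prop_negative <- ifelse(const$n_entries > 0, 0.5, NA_real_)
  cc <- center_series(const, "negative")
  expect_true(all(abs(cc$centered[!is.na(cc$centered)]) < 1e-12))
  # missing stays missing
  expect_identical(is.na(cs$centered), s$n_entries == 0)
})

test_that("period split uses -A..0 acute and -30..-(A+1) baseline with truncation", {
  g <- generate_participant(null_config(seed = 13, pid = "PS1", days = 60,
                                        mean = 10))
  s <- daily_metrics(g$record, g$truth$labels)
  sp <- split_periods(s, A = 10)
  expect_equal(nrow(sp$acute), 11)              # -10..0 inclusive
  expect_equal(range(sp$acute$day_index), c(-10, 0))
  expect_equal(nrow(sp$baseline), 20)           # -30..-11
  expect_equal(range(sp$baseline$day_index), c(-30, -11))
  expect_true(length(intersect(sp$acute$date, sp$baseline$date)) == 0)
  # enrollment only 10 days before hospitalization: baseline empty
  g5 <- generate_participant(
    synthetic_config(participant_id = "CASE5", study_days = 11,
                     hospitalization_day = 11, entries_per_day_mean = 10,
                     elevation_onset_days_before = 5, missing_day_prob = 0,
                     rng_seed = 55))
  s5 <- daily_metrics(g5$record, g5$truth$labels)
  sp5 <- split_periods(s5, A = 10)
  expect_equal(nrow(sp5$baseline), 0)
  expect_equal(nrow(sp5$acute), 11)
  # A = 30 empties the baseline by construction
  expect_equal(nrow(split_periods(s, A = 30)$baseline), 0)
  expect_error(split_periods(s, A = 0), "positive")
})

test_that("window ratio reproduces forced arithmetic and the homogeneous null", {
  # toy counts: window 3 days 300 entries/6 flags, study 3000 entries/6 flags
  dates <- seq(as.Date("2023-01-02"), by = "day", length.out = 12)
  s <- tibble::tibble(
    participant_id = "W1", date = dates,
    day_index = as.integer(dates - dates[12]),
    n_entries = c(rep(300L, 9), rep(100L, 3)),
    n_suicide = c(rep(0L, 9), rep(2L, 3)),
    n_negative = 0L, n_neg_selfref = 0L,
    prop_suicide = c(rep(0, 9), rep(2 / 100, 3)),
    prop_negative = 0, prop_neg_selfref = 0)
  crv <- window_ratio_curve(s, "suicide", w_max = 12)
  expect_equal(crv$ratio[3], (6 / 300) / (6 / 3000))  # forced arithmetic: 10
  # homogeneous stream: R_w near 1 for all w
  g <- generate_participant(null_config(seed = 77, pid = "N1", days = 90,
                                        mean = 200))
  sn <- daily_metrics(g$record, g$truth$labels)
  crv_n <- window_ratio_curve(sn, "negative", w_max = 30)
  expect_true(all(abs(crv_n$ratio - 1) < 0.35))
  expect_lt(abs(crv_n$ratio[30] - 1), 0.1)
  # zero study-wide flags: undefined curve with a warning, not an error
  z <- s; z$n_suicide[] <- 0L; z$prop_suicide[] <- 0
  expect_warning(crv_z <- window_ratio_curve(z, "suicide"), "undefined")
  expect_true(all(is.na(crv_z$ratio)))
})

test_that("injected elevation is recovered by the ratio curve at the right window", {
  cfg <- null_config(seed = 88, pid = "EL1", days = 90, mean = 300,
                     elevation_suicide = 5, elevation_onset_days_before = 4)
  g <- generate_participant(cfg)
  s <- daily_metrics(g$record, g$truth$labels)
  crv <- window_ratio_curve(s, "suicide", w_max = 30)
  expect_equal(crv$ratio[5], expected_window_ratio(cfg, 5), tolerance = 0.25)
  expect_gt(crv$ratio[5], crv$ratio[15])
  expect_gt(crv$ratio[15], crv$ratio[30])
})

test_that("group smoothing interpolates constants and tracks a unimodal signal", {
  const_curves <- dplyr::bind_rows(lapply(c("a", "b", "c"), function(p) {
    tibble::tibble(participant_id = p, metric = "suicide", w = 1:30,
                   window_frequency = 0.04, ratio = 2)
  }))
  sm <- group_smooth(const_curves)
  expect_true(all(abs(sm$fit - 2) < 1e-8))
  expect_error(group_smooth(const_curves[const_curves$participant_id == "a", ]),
               "at least 2")
  # unimodal pooled signal: smoothed argmax stays in the peak region
  set.seed(5)
  shape <- 1 + 2 * exp(-((1:30) - 6)^2 / 18)
  curves <- dplyr::bind_rows(lapply(1:6, function(i) {
    tibble::tibble(participant_id = paste0("u", i), metric = "suicide",
                   w = 1:30, window_frequency = NA_real_,
                   ratio = shape + rnorm(30, 0, 0.1))
  }))
  sm2 <- group_smooth(curves, span = 0.5)
  # oracle: local-mean smoother over pooled points
  pooled <- curves |> dplyr::group_by(w) |> dplyr::summarise(m = mean(ratio))
  oracle_sm <- vapply(1:30, function(x) {
    mean(pooled$m[abs(pooled$w - x) <= 4])
  }, numeric(1))
  expect_lte(abs(sm2$w[which.max(sm2$fit)] - which.max(oracle_sm)), 2)
  # large span approaches the global linear weighted least squares fit
  sm_lin <- group_smooth(dplyr::bind_rows(lapply(c("x", "y"), function(p) {
    tibble::tibble(participant_id = p, metric = "m", w = 1:30,
                   window_frequency = NA_real_, ratio = 0.5 + 0.1 * (1:30))
  })), span = 1e6)
  expect_true(all(abs(sm_lin$fit - (0.5 + 0.1 * (1:30))) < 1e-6))
})

test_that("time-of-day stratification partitions the day and conserves counts", {
  g <- generate_participant(null_config(seed = 19, pid = "TD1", days = 20,
                                        mean = 50))
  labels <- g$truth$labels
  tod <- time_of_day_metrics(g$record, labels)
  expect_setequal(unique(tod$tod_bin),
                  c("midnight", "morning", "afternoon", "evening"))
  # conservation: per-day bin counts sum to the unstratified counts
  s <- daily_metrics(g$record, labels)
  summed <- tod |> dplyr::group_by(date) |>
    dplyr::summarise(n = sum(n_entries), ns = sum(n_suicide))
  expect_equal(summed$n, s$n_entries)
  expect_equal(summed$ns, s$n_suicide)
  expect_error(time_of_day_metrics(g$record, labels, bin_edges = c(0, 6, 12, 24)),
               "partition")
  # all mass in one bin when the generator only emits midnight entries
  gm <- generate_participant(null_config(seed = 3, pid = "TDM", days = 10,
                                         mean = 20,
                                         diurnal_weights = c(morning = 0,
                                                             afternoon = 0,
                                                             evening = 0,
                                                             midnight = 1)))
  todm <- time_of_day_metrics(gm$record, gm$truth$labels)
  expect_true(all(todm$n_entries[todm$tod_bin != "midnight"] == 0))
  expect_true(sum(todm$n_entries[todm$tod_bin == "midnight"]) ==
                nrow(gm$record$entries))
})

test_that("weekday/weekend partition is a calendar fact and conserves totals", {
  g <- generate_participant(null_config(seed = 29, pid = "WW1", days = 60,
                                        mean = 50))
  s <- daily_metrics(g$record, g$truth$labels)
  # 7 consecutive days always contain 2 weekend + 5 weekday days
  week <- s[s$day_index %in% -6:0, ]
  expect_equal(sum(acutelang:::is_weekend(week$date)), 2)
  ww <- weekday_weekend_metrics(s, A = 10)
  study <- ww[ww$period == "study", ]
  per_metric <- study |> dplyr::group_by(metric) |>
    dplyr::summarise(n = sum(n_entries), f = sum(n_flagged))
  expect_true(all(per_metric$n == sum(s$n_entries)))
  expect_equal(per_metric$f[per_metric$metric == "suicide"], sum(s$n_suicide))
})

test_that("weekend multiplier on suicide language is recovered from acute pooled frequencies", {
  cfgs <- lapply(1:12, function(i) {
    null_config(seed = 300 + i, pid = sprintf("WK%02d", i), days = 90,
                mean = 150, weekend_multiplier_suicide = 3)
  })
  cohort <- generate_cohort(cfgs)
  ww <- dplyr::bind_rows(lapply(cohort, function(g) {
    weekday_weekend_metrics(daily_metrics(g$record, g$truth$labels), A = 10)
  }))
  acute <- ww[ww$period == "acute" & ww$metric == "suicide", ]
  agg <- acute |> dplyr::group_by(partition) |>
    dplyr::summarise(n = sum(n_entries), f = sum(n_flagged))
  p_we <- agg$f[agg$partition == "weekend"] / agg$n[agg$partition == "weekend"]
  p_wd <- agg$f[agg$partition == "weekday"] / agg$n[agg$partition == "weekday"]
  ratio <- p_we / p_wd
  se_log <- sqrt((1 - p_we) / agg$f[agg$partition == "weekend"] +
                   (1 - p_wd) / agg$f[agg$partition == "weekday"])
  expect_lt(abs(log(ratio / 3)), 3 * se_log)
})

test_that("day coverage counts days with entries and respects the window", {
  g <- generate_participant(null_config(seed = 37, pid = "CV1", days = 30,
                                        mean = 20))
  expect_equal(day_coverage(g$record), 1)
  gm <- generate_participant(
    synthetic_config(participant_id = "CV2", study_days = 100,
                     hospitalization_day = 90, entries_per_day_mean = 20,
                     missing_day_prob = 0.5, rng_seed = 44))
  cov <- day_coverage(gm$record)
  se <- sqrt(0.5 * 0.5 / 100)
  expect_lt(abs(cov - 0.5), 3 * se)
  expect_error(day_coverage(g$record, as.Date(c("2022-01-01", "2023-01-05"))),
               "within the study span")
})
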
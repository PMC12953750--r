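#' @import ggplot2
NULL

.save_maybe <- function(p, file, width = 8, height = 5) {
  if (!is.null(file)) ggsave(file, p, width = width, height = height)
  p
}

#' Case panel: centered daily series around hospitalization
#'
#' Centered daily proportions over days -30..0 with acute/baseline shading,
#' the study-mean reference (dashed line at 0 after centering) and a red
#' vertical marker at Day 0, the hospitalization day. A participant with no
#' baseline history renders acute-only.
#'
#' @param series a [daily_metrics()] tibble.
#' @param metric metric name.
#' @param A acute window length (default 10).
#' @param file optional output file (format by extension).
#' @return a ggplot object (written to `file` if given).
#' @export
render_case_panel <- function(series, metric, A = 10, file = NULL) {
  if (sum(series$n_entries) == 0) stop("empty series", call. = FALSE)
  cs <- center_series(series, metric)
  cs <- cs[cs$day_index >= -30 & cs$day_index <= 0, ]
  has_baseline <- any(cs$day_index <= -(A + 1))
  shade <- tibble(
    xmin = c(if (has_baseline) min(cs$day_index) else NULL, -A),
    xmax = c(if (has_baseline) -(A + 1) else NULL, 0),
    period = c(if (has_baseline) "baseline" else NULL, "acute")
  )
  p <- ggplot(cs, aes(x = .data$day_index, y = .data$centered)) +
    geom_rect(data = shade,
              aes(xmin = .data$xmin, xmax = .data$xmax, fill = .data$period),
              ymin = -Inf, ymax = Inf, alpha = 0.15, inherit.aes = FALSE) +
    geom_hline(yintercept = 0, linetype = "dashed") +
    geom_vline(xintercept = 0, colour = "red") +
    geom_line(na.rm = TRUE) +
    geom_point(size = 0.8, na.rm = TRUE) +
    scale_fill_manual(values = c(acute = "red", baseline = "steelblue")) +
    labs(x = "Day relative to hospitalization (Day 0)",
         y = sprintf("Centered daily proportion (%s)", metric),
         title = sprintf("%s - %s", cs$participant_id[1], metric),
         fill = "Period") +
    theme_minimal()
  .save_maybe(p, file)
}

#' Window-ratio sensitivity curves with group smooth
#'
#' Thin lines per participant, the group-level loess fit with its pointwise
#' band in red, and a dashed reference at ratio 1 (equivalence between the
#' acute window and the study mean).
#'
#' @param curves combined [window_ratio_curve()] tibble (one metric).
#' @param smoothed optional [group_smooth()] output; computed when `NULL`
#'   and two or more participants are present.
#' @param file optional output file.
#' @return a ggplot object.
#' @export
render_ratio_curves <- function(curves, smoothed = NULL, file = NULL) {
  if (is.list(curves) && !is.data.frame(curves)) curves <- bind_rows(curves)
  if (is.null(smoothed) && length(unique(curves$participant_id)) >= 2) {
    smoothed <- group_smooth(curves)
  }
  p <- ggplot(curves, aes(x = .data$w, y = .data$ratio,
                          group = .data$participant_id)) +
    geom_hline(yintercept = 1, linetype = "dashed") +
    geom_line(alpha = 0.5, linewidth = 0.3, na.rm = TRUE)
  if (!is.null(smoothed)) {
    p <- p +
      geom_ribbon(data = smoothed,
                  aes(x = .data$w, ymin = .data$lower, ymax = .data$upper),
                  inherit.aes = FALSE, fill = "red", alpha = 0.2) +
      geom_line(data = smoothed, aes(x = .data$w, y = .data$fit),
                inherit.aes = FALSE, colour = "red", linewidth = 1)
  }
  p <- p +
    labs(x = "Acute window length w (days, including Day 0)",
         y = "Within-person frequency ratio",
         title = unique(curves$metric)[1]) +
    theme_minimal()
  .save_maybe(p, file)
}

#' Topic frequency trajectories
#'
#' One facet per selected topic; the dotted reference line is the topic's
#' mean frequency over the entire study.
#'
#' @param freqs [topic_frequencies()] output for one participant.
#' @param selected_topics topics to facet (default: all non-OUTLIER).
#' @param file optional output file.
#' @return a ggplot object.
#' @export
render_topic_trajectories <- function(freqs, selected_topics = NULL,
                                      file = NULL) {
  topics <- selected_topics %||% setdiff(unique(freqs$topic), "OUTLIER")
  df <- freqs[freqs$topic %in% topics, ]
  if (nrow(df) == 0) stop("empty series", call. = FALSE)
  means <- df |>
    group_by(.data$topic) |>
    summarise(mu = sum(.data$count) / sum(.data$n_entries[!duplicated(.data$date)]),
              .groups = "drop")
  p <- ggplot(df, aes(x = .data$day_index, y = .data$proportion)) +
    geom_line(na.rm = TRUE) +
    geom_hline(data = means, aes(yintercept = .data$mu), linetype = "dotted") +
    geom_vline(xintercept = 0, colour = "red") +
    facet_wrap(~topic, scales = "free_y") +
    labs(x = "Day relative to hospitalization",
         y = "Daily topic proportion",
         title = df$participant_id[1]) +
    theme_minimal()
  .save_maybe(p, file, width = 9, height = 6)
}

#' Clinician timeline aligned with NLP signal heatmap
#'
#' Per-day signal intensity (daily proportions of the given metrics) as a
#' red-blue heatmap with clinician-coded events overlaid as colour-coded
#' rows above it.
#'
#' @param events annotation tibble (one participant).
#' @param series that participant's [daily_metrics()].
#' @param metrics metric names to show (default suicide and negative).
#' @param window day-index window (default -10..0, the acute period).
#' @param file optional output file.
#' @return a ggplot object.
#' @export
render_timeline_heatmap <- function(events, series,
                                    metrics = c("suicide", "negative"),
                                    window = c(-10, 0), file = NULL) {
  s <- series[series$day_index >= window[1] & series$day_index <= window[2], ]
  if (nrow(s) == 0 || sum(s$n_entries) == 0) stop("empty series", call. = FALSE)
  heat <- bind_rows(lapply(metrics, function(m) {
    cols <- .metric_cols(m)
    mu <- study_mean(series, m, "pooled")
    tibble(date = s$date, day_index = s$day_index, row = m,
           value = (s[[cols$prop_col]] - mu) / max(mu, .Machine$double.eps))
  }))
  ev <- as_tibble(events)
  ev$day_index <- as.integer(ev$date - series$date[series$day_index == 0])
  ev <- ev[ev$day_index >= window[1] & ev$day_index <= window[2], ]
  levels_y <- c(rev(metrics), sort(unique(ev$category)))
  heat$yrow <- factor(heat$row, levels = levels_y)
  p <- ggplot() +
    geom_tile(data = heat,
              aes(x = .data$day_index, y = .data$yrow, fill = .data$value)) +
    scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                         midpoint = 0, na.value = "grey90") +
    labs(x = "Day relative to hospitalization", y = NULL,
         fill = "Relative\nelevation") +
    theme_minimal()
  if (nrow(ev)) {
    ev$yrow <- factor(ev$category, levels = levels_y)
    p <- p + geom_point(data = ev,
                        aes(x = .data$day_index, y = .data$yrow,
                            colour = .data$category),
                        size = 3, shape = 15) +
      labs(colour = "Event category")
  }
  .save_maybe(p, file, width = 9, height = 4)
}
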
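# Cohort-level event summaries and duration aggregation.

round_rate <- function(x) ifelse(x > 10, signif(x, 2), round(x, 1))

#' Cohort summary of convergence events
#'
#' Tabulates convergence events over a cohort of recordings: how many
#' recordings (and unique pairs) showed at least one event, repeated
#' events, or events at multiple ratios, plus per-recording and
#' per-unique-pair event rates. Repeat recordings of the same pair are
#' linked through the `recordings` map.
#'
#' Proportions are reported as whole percentages; rates to one decimal
#' place (two significant figures above 10), matching the conventional
#' presentation of such tables.
#'
#' @param events A tibble of events with columns `recording_id` and
#'   `label` (as produced by [detect_events()] plus a `recording_id`,
#'   e.g. via [run_pipeline()]). May be empty.
#' @param recordings Cohort map: a data frame with one row per recording,
#'   columns `recording_id` and `pair_id` (every cohort recording,
#'   including event-free ones).
#' @return A one-row `cohort_event_summary` tibble with columns
#'   `recordings_total`, `recordings_with_event`, `pct_with_event`,
#'   `recordings_multi_event`, `pct_multi_event`,
#'   `recordings_multi_ratio`, `pct_multi_ratio`, `pairs_total`,
#'   `pairs_with_event`, `pct_pairs_with_event`, `pairs_multi_ratio`,
#'   `pct_pairs_multi_ratio`, `events_total`, `events_per_recording`,
#'   `events_per_pair`.
#' @examples
#' recs <- tibble::tibble(recording_id = as.character(1:30),
#'                        pair_id = as.character(rep(1:18, length.out = 30)))
#' ev <- tibble::tibble(recording_id = rep("1", 39), label = "1:1")
#' summarize_cohort(ev, recs)$events_per_recording # 39/30 = 1.3
#' @export
summarize_cohort <- function(events, recordings) {
  recordings <- as_tibble(recordings) |> distinct(.data$recording_id, .data$pair_id)
  if (anyDuplicated(recordings$recording_id)) {
    abort("Each recording_id must map to exactly one pair_id.")
  }
  n_rec <- nrow(recordings)
  n_pair <- n_distinct(recordings$pair_id)
  if (n_rec == 0) abort("`recordings` is empty.")
  if (is.null(events) || nrow(events) == 0) {
    events <- tibble(recording_id = character(), label = character())
  }
  events <- as_tibble(events)[, c("recording_id", "label")]
  if (!all(events$recording_id %in% recordings$recording_id)) {
    abort("Events reference recordings missing from the cohort map.")
  }
  by_rec <- events |>
    count(.data$recording_id, name = "n_events") |>
    left_join(events |> distinct(.data$recording_id, .data$label) |>
                count(.data$recording_id, name = "n_ratios"),
              by = "recording_id")
  by_pair <- events |>
    left_join(recordings, by = "recording_id") |>
    group_by(.data$pair_id) |>
    summarise(n_events = n(), n_ratios = n_distinct(.data$label))
  n_total <- nrow(events)
  out <- tibble(
    recordings_total = n_rec,
    recordings_with_event = nrow(by_rec),
    pct_with_event = round(100 * nrow(by_rec) / n_rec),
    recordings_multi_event = sum(by_rec$n_events > 1),
    pct_multi_event = round(100 * sum(by_rec$n_events > 1) / n_rec),
    recordings_multi_ratio = sum(by_rec$n_ratios > 1),
    pct_multi_ratio = round(100 * sum(by_rec$n_ratios > 1) / n_rec),
    pairs_total = n_pair,
    pairs_with_event = nrow(by_pair),
    pct_pairs_with_event = round(100 * nrow(by_pair) / n_pair),
    pairs_multi_ratio = sum(by_pair$n_ratios > 1),
    pct_pairs_multi_ratio = round(100 * sum(by_pair$n_ratios > 1) / n_pair),
    events_total = n_total,
    events_per_recording = round_rate(n_total / n_rec),
    events_per_pair = round_rate(n_total / n_pair))
  class(out) <- c("cohort_event_summary", class(out))
  out
}

#' Per-recording aggregated convergence durations
#'
#' Sums event durations within each recording to the aggregate
#' convergence time gamma. Only recordings in which convergence was
#' observed appear (event-free recordings contribute gamma = 0 and are
#' excluded, matching how aggregate-duration distributions are reported);
#' set `keep_empty = TRUE` (with a `recordings` map) to retain them.
#'
#' @param events Events tibble with `recording_id` and `duration_s`.
#' @param recordings Optional cohort map (needed for `keep_empty`).
#' @param keep_empty Retain event-free recordings with `gamma_s = 0`?
#' @return A tibble: `recording_id`, `n_events`, `gamma_s`.
#' @export
aggregate_durations <- function(events, recordings = NULL,
                                keep_empty = FALSE) {
  out <- events |>
    group_by(.data$recording_id) |>
    summarise(n_events = n(), gamma_s = sum(.data$duration_s)) |>
    arrange(.data$recording_id)
  if (keep_empty) {
    if (is.null(recordings)) {
      abort("`recordings` is required when keep_empty = TRUE.")
    }
    out <- as_tibble(recordings) |>
      distinct(.data$recording_id) |>
      left_join(out, by = "recording_id") |>
      mutate(n_events = coalesce(.data$n_events, 0L),
             gamma_s = coalesce(.data$gamma_s, 0))
  }
  out
}

#' Distribution summary of individual event durations
#'
#' @param events Events tibble with a `duration_s` column.
#' @return One-row tibble: `n`, `mean_s`, `se_s`, `median_s`, `q1_s`,
#'   `q3_s`, `max_s`.
#' @export
duration_stats <- function(events) {
  d <- events$duration_s
  tibble(n = length(d),
         mean_s = mean(d), se_s = sd(d) / sqrt(length(d)),
         median_s = median(d),
         q1_s = unname(quantile(d, 0.25)), q3_s = unname(quantile(d, 0.75)),
         max_s = if (length(d)) max(d) else NA_real_)
}
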
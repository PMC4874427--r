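# broom-style tidiers for the package's result objects.

#' Tidy a synthetic pair's ground truth
#'
#' @param x A `synthetic_pair`.
#' @param ... Unused.
#' @return The truth tibble (one row per scripted event).
#' @export
tidy.synthetic_pair <- function(x, ...) x$truth

#' @rdname tidy.synthetic_pair
#' @export
glance.synthetic_pair <- function(x, ...) {
  tibble(n_samples = nrow(x$trace_a),
         duration_s = nrow(x$trace_a) / sample_rate(x$trace_a),
         n_scripted_events = nrow(x$truth),
         scripted_time_s = sum(x$truth$end_s - x$truth$start_s),
         seed = x$seed %||% NA_integer_)
}

#' Tidy detected convergence events
#'
#' @param x A `convergence_events` tibble.
#' @param ... Unused.
#' @return `tidy()` returns the events as a plain tibble; `glance()`
#'   a one-row summary (event count, ratios observed, total and mean
#'   convergence time with standard error, duration quartiles).
#' @export
tidy.convergence_events <- function(x, ...) as_tibble(x)

#' @rdname tidy.convergence_events
#' @export
glance.convergence_events <- function(x, ...) {
  d <- x$duration_s
  tibble(n_events = nrow(x),
         n_ratios = n_distinct(x$label),
         total_convergence_s = sum(d),
         mean_duration_s = if (length(d)) mean(d) else NA_real_,
         se_duration_s = if (length(d) > 1) sd(d) / sqrt(length(d)) else NA_real_,
         median_duration_s = if (length(d)) median(d) else NA_real_,
         q1_duration_s = if (length(d)) unname(quantile(d, 0.25)) else NA_real_,
         q3_duration_s = if (length(d)) unname(quantile(d, 0.75)) else NA_real_)
}

#' Tidy a cohort event summary into long form
#'
#' @param x A `cohort_event_summary`.
#' @param ... Unused.
#' @return A two-column tibble (`metric`, `value`).
#' @export
tidy.cohort_event_summary <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' Tidy cohort flight statistics
#'
#' @param x A `cohort_flight_stats`.
#' @param ... Unused.
#' @return `tidy()` returns the per-recording means/SDs/IQRs underlying
#'   the summary; `glance()` the one-row cohort summary itself.
#' @export
tidy.cohort_flight_stats <- function(x, ...) attr(x, "per_recording")

#' @rdname tidy.cohort_flight_stats
#' @export
glance.cohort_flight_stats <- function(x, ...) as_tibble(x)
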
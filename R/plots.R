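# ggplot2 displays for traces, ratio series, distributions, waterfalls.

#' @importFrom ggplot2 ggplot aes geom_line geom_rect geom_col geom_step
#'   geom_tile labs scale_fill_viridis_c facet_wrap theme_minimal
#'   geom_hline annotate
NULL

#' Plot a frequency trace
#'
#' Line plot of the instantaneous fundamental (optionally with selected
#' harmonics); invalid samples are blanked.
#'
#' @param object A [freq_trace()].
#' @param harmonics Integer harmonics to draw (default 1).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.freq_trace <- function(object, harmonics = 1, ...) {
  df <- purrr::map_dfr(harmonics, function(k) {
    tibble(time_s = object$time_s,
           freq_hz = ifelse(object$valid, object$omega_hz * k, NA_real_),
           harmonic = factor(k))
  })
  ggplot(df, aes(.data$time_s, .data$freq_hz, colour = .data$harmonic)) +
    geom_line(na.rm = TRUE) +
    labs(x = "time (s)", y = "frequency (Hz)", colour = "harmonic") +
    theme_minimal()
}

#' Plot a pairwise ratio series with tolerance bands
#'
#' @param object A `ratio_series`.
#' @param bands Optional tibble of tolerance bands (from
#'   [tolerance_band()] or a [detection_config()]'s `bands`) drawn as
#'   shaded ribbons.
#' @param events Optional `convergence_events` drawn as shaded spans.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ratio_series <- function(object, bands = NULL, events = NULL, ...) {
  df <- tibble(time_s = object$time_s,
               ratio = ifelse(object$valid, object$ratio, NA_real_))
  p <- ggplot(df, aes(.data$time_s, .data$ratio))
  if (!is.null(bands)) {
    p <- p + geom_rect(data = bands,
                       aes(xmin = -Inf, xmax = Inf,
                           ymin = .data$lo, ymax = .data$hi),
                       inherit.aes = FALSE, alpha = 0.15, fill = "steelblue")
  }
  if (!is.null(events) && nrow(events)) {
    p <- p + geom_rect(data = as_tibble(events),
                       aes(xmin = .data$start_s, xmax = .data$end_s,
                           ymin = -Inf, ymax = Inf),
                       inherit.aes = FALSE, alpha = 0.2, fill = "tomato")
  }
  p + geom_line(na.rm = TRUE) +
    labs(x = "time (s)", y = "frequency ratio") +
    theme_minimal()
}

#' Plot a cohort distribution
#'
#' @param object A `cohort_distribution`.
#' @param bands Optional tolerance bands marked as shaded strips.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cohort_distribution <- function(object, bands = NULL, ...) {
  p <- ggplot(object, aes(.data$bin_left, .data$density))
  if (!is.null(bands)) {
    p <- p + geom_rect(data = bands,
                       aes(xmin = .data$lo, xmax = .data$hi,
                           ymin = -Inf, ymax = Inf),
                       inherit.aes = FALSE, alpha = 0.15, fill = "steelblue")
  }
  p + geom_step() +
    labs(x = "value", y = "density") +
    theme_minimal()
}

#' Waterfall plot of windowed frequency histograms
#'
#' Stacks the per-window frequency distributions of one or two subjects
#' through time, the classic display of harmonic convergence at a shared
#' overtone.
#'
#' @param h_a A `windowed_hist`.
#' @param h_b Optional second `windowed_hist` on the same grid.
#' @return A ggplot (time on the y axis, frequency on the x axis, tile
#'   alpha giving probability mass).
#' @export
plot_waterfall <- function(h_a, h_b = NULL) {
  df <- mutate(as_tibble(h_a), subject = "a")
  if (!is.null(h_b)) df <- bind_rows(df, mutate(as_tibble(h_b), subject = "b"))
  ggplot(df, aes(.data$bin_left, .data$t_start,
                 alpha = .data$prob, fill = .data$subject)) +
    geom_tile(width = attr(h_a, "bin_hz"),
              height = attr(h_a, "window_s") * 0.9) +
    labs(x = "frequency (Hz)", y = "time (s)", alpha = "mass") +
    theme_minimal()
}

#' Plot an overlap series
#'
#' @param object An `overlap_series`.
#' @param ... Unused.
#' @return A ggplot of the per-window histogram overlap through time.
#' @export
autoplot.overlap_series <- function(object, ...) {
  ggplot(object, aes(.data$t_start, .data$alpha)) +
    geom_step() +
    labs(x = "time (s)", y = "overlap fraction") +
    theme_minimal()
}

#' Plot a local coefficient-of-variation series
#'
#' @param object A `cv_series`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cv_series <- function(object, ...) {
  df <- tibble(time_s = object$time_s,
               cv = ifelse(object$valid, object$cv, NA_real_))
  ggplot(df, aes(.data$time_s, .data$cv)) +
    geom_line(na.rm = TRUE) +
    labs(x = "time (s)", y = expression(c[v])) +
    theme_minimal()
}
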
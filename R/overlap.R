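# Windowed frequency histograms and the histogram-intersection overlap.

#' Windowed frequency histograms of a harmonic trace
#'
#' Splits a trace's k-th harmonic into consecutive non-overlapping time
#' windows and histograms the valid samples of each on a shared,
#' integer-aligned bin grid (edges at multiples of `bin_hz` starting from
#' 0). Each window's counts are normalized to sum to one, producing the
#' per-window frequency distributions stacked in waterfall displays.
#'
#' @param trace A [freq_trace()].
#' @param k Harmonic number (default 1, the fundamental); e.g. use the
#'   male second and female third harmonics when comparing an
#'   opposite-sex pair at its shared overtone.
#' @param window_s Window length (s), default 1; windows do not overlap.
#' @param bin_hz Frequency resolution (Hz), default 1.
#' @return A `windowed_hist` tibble in long form: `window`, `t_start`,
#'   `bin_left`, `prob` (only occupied bins are stored). Windows without
#'   any valid sample are flagged in the `windows` attribute tibble
#'   (`window`, `t_start`, `n_valid`, `ok`) and carry no probability
#'   mass. Attributes `window_s` and `bin_hz` define the shared grid.
#' @export
windowed_histograms <- function(trace, k = 1, window_s = 1, bin_hz = 1) {
  if (window_s <= 0 || bin_hz <= 0) {
    abort("`window_s` and `bin_hz` must be positive.")
  }
  if (!any(trace$valid)) abort("Trace has no valid samples.")
  fs <- sample_rate(trace)
  tr <- harmonic_trace(trace, k)
  L <- max(1L, round(window_s * fs))
  win <- (seq_len(nrow(tr)) - 1L) %/% L + 1L
  df <- tibble(window = win,
               bin_left = floor(tr$omega_hz / bin_hz) * bin_hz,
               valid = tr$valid)
  meta <- df |>
    group_by(.data$window) |>
    summarise(n_valid = sum(.data$valid)) |>
    mutate(t_start = tr$time_s[1] + (.data$window - 1) * L / fs,
           ok = .data$n_valid > 0)
  hist <- df |>
    filter(.data$valid) |>
    count(.data$window, .data$bin_left) |>
    group_by(.data$window) |>
    mutate(prob = .data$n / sum(.data$n)) |>
    ungroup() |>
    left_join(meta |> select("window", "t_start"), by = "window") |>
    select("window", "t_start", "bin_left", "prob")
  new_series(hist, "windowed_hist", fs,
             window_s = window_s, bin_hz = bin_hz, windows = meta,
             harmonic = k)
}

#' Histogram-overlap series between two windowed histograms
#'
#' Per window, the overlap `alpha = sum_i min(a_i, b_i)` between the two
#' normalized frequency histograms over their `m` shared bins (histogram
#' intersection). `alpha` lies in `[0, 1]`, equals 1 for identical
#' histograms and 0 for disjoint supports, and is symmetric in its
#' arguments; rising overlap through time is the waterfall signature of
#' harmonic convergence.
#'
#' @param h_a,h_b `windowed_hist` objects on identical window and bin
#'   grids (same `window_s`, `bin_hz`, and window time stamps).
#' @return An `overlap_series` tibble: `window`, `t_start`, `alpha` (one
#'   row per window in which both histograms have valid samples).
#' @export
overlap_series <- function(h_a, h_b) {
  for (at in c("window_s", "bin_hz")) {
    if (!isTRUE(all.equal(attr(h_a, at), attr(h_b, at)))) {
      abort(sprintf("Bin-grid mismatch: `%s` differs between the histograms.", at))
    }
  }
  wa <- attr(h_a, "windows"); wb <- attr(h_b, "windows")
  shared <- inner_join(wa |> filter(.data$ok) |> select("window", "t_start"),
                       wb |> filter(.data$ok) |> select("window", "t_start"),
                       by = "window", suffix = c("", "_b"))
  if (nrow(shared) && any(abs(shared$t_start - shared$t_start_b) > 1e-9)) {
    abort("Bin-grid mismatch: window time stamps differ.")
  }
  joined <- full_join(h_a |> select("window", "bin_left", a = "prob"),
                      h_b |> select("window", "bin_left", b = "prob"),
                      by = c("window", "bin_left")) |>
    mutate(a = coalesce(.data$a, 0), b = coalesce(.data$b, 0))
  out <- joined |>
    semi_join(shared, by = "window") |>
    group_by(.data$window) |>
    summarise(alpha = sum(pmin(.data$a, .data$b))) |>
    left_join(shared |> select("window", "t_start"), by = "window") |>
    select("window", "t_start", "alpha")
  new_series(out, "overlap_series", 1 / attr(h_a, "window_s"))
}
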
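#' Local coefficient of variation of a frequency trace
#'
#' Short-time flight-tone variability: a centred rectangular sliding
#' window (default 0.25 s) yields a moving sample standard deviation and
#' moving mean, whose ratio `c_v(t) = sigma(t) / mu(t)` is a
#' dimensionless, scale-free dispersion measure — `c_v` of `k * omega`
#' equals `c_v` of `omega` for any `k > 0`, which makes traces of
#' individuals with very different mean wing-beat frequencies
#' comparable.
#'
#' Samples within half a window of an edge or of any invalid sample are
#' masked; windows with non-positive mean are masked with a warning.
#'
#' @param trace A [freq_trace()].
#' @param window_s Sliding-window length (s), default 0.25.
#' @return A `cv_series` tibble: `time_s`, `cv`, `valid`.
#' @export
local_cv <- function(trace, window_s = 0.25) {
  if (window_s <= 0) abort("`window_s` must be positive.")
  fs <- sample_rate(trace)
  n <- nrow(trace)
  k <- max(3L, round(window_s * fs))
  k <- k + (k %% 2 == 0) # odd, centred
  if (k > n) abort("`window_s` exceeds the trace duration.")
  x <- trace$omega_hz
  kern <- rep(1, k)
  msum <- as.numeric(stats::filter(x, kern, sides = 2))
  msq <- as.numeric(stats::filter(x^2, kern, sides = 2))
  nvalid <- as.numeric(stats::filter(as.numeric(trace$valid), kern, sides = 2))
  mu <- msum / k
  var <- pmax((msq - k * mu^2) / (k - 1), 0)
  cv <- sqrt(var) / mu
  valid <- !is.na(msum) & nvalid == k & mu > 0
  if (any(!is.na(mu) & nvalid == k & mu <= 0)) {
    warn("Windows with non-positive mean frequency were masked.")
  }
  cv[!valid] <- NA_real_
  new_series(tibble(time_s = trace$time_s, cv = cv, valid = valid),
             "cv_series", fs, window_s = window_s)
}

#' Cohort flight statistics
#'
#' Summary statistics of fundamental wing-beat frequency over a cohort
#' of recordings, separating within-recording from between-recording
#' dispersion: the cohort mean `mu` of per-recording means with its
#' range, `sigma_intra` (mean within-recording standard deviation),
#' `sigma_inter` (standard deviation of per-recording means), and the
#' mean within-recording inter-quartile range with its range.
#'
#' @param traces A named list of [freq_trace()]s (names are recording
#'   ids), or a long tibble with columns `recording_id`, `omega_hz`,
#'   `valid`.
#' @return A one-row `cohort_flight_stats` tibble: `n_recordings`, `mu`,
#'   `mu_min`, `mu_max`, `sigma_intra`, `sigma_inter`, `iqr_intra`,
#'   `iqr_min`, `iqr_max`. `sigma_inter` is `NA` for a single recording.
#'   Recordings without valid samples are excluded with a warning.
#' @export
cohort_flight_stats <- function(traces) {
  if (is.data.frame(traces)) {
    long <- as_tibble(traces)
  } else {
    if (is.null(names(traces))) {
      names(traces) <- sprintf("rec%02d", seq_along(traces))
    }
    long <- purrr::imap_dfr(traces, function(tr, id) {
      tibble(recording_id = id, omega_hz = tr$omega_hz, valid = tr$valid)
    })
  }
  per <- long |>
    filter(.data$valid) |>
    group_by(.data$recording_id) |>
    summarise(mean_hz = mean(.data$omega_hz),
              sd_hz = sd(.data$omega_hz),
              iqr_hz = IQR(.data$omega_hz))
  dropped <- setdiff(unique(long$recording_id), per$recording_id)
  if (length(dropped)) {
    warn(sprintf("Excluded %d recording(s) without valid samples: %s",
                 length(dropped), paste(dropped, collapse = ", ")))
  }
  if (nrow(per) == 0) abort("No recording has valid samples.")
  out <- tibble(
    n_recordings = nrow(per),
    mu = mean(per$mean_hz),
    mu_min = min(per$mean_hz), mu_max = max(per$mean_hz),
    sigma_intra = mean(per$sd_hz),
    sigma_inter = if (nrow(per) > 1) sd(per$mean_hz) else NA_real_,
    iqr_intra = mean(per$iqr_hz),
    iqr_min = min(per$iqr_hz), iqr_max = max(per$iqr_hz))
  if (nrow(per) == 1) inform("Single recording: `sigma_inter` is undefined.")
  attr(out, "per_recording") <- per
  class(out) <- c("cohort_flight_stats", class(out))
  out
}
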
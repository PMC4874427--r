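#' Piecewise aggregate approximation (PAA) of a series
#'
#' Reduces a sampled series to the means of consecutive equal-length
#' frames: frame `i` of a window-`w` reduction holds the mean of the
#' frame's valid samples. A trailing partial frame is kept and averaged
#' over the samples it has. Frames whose fraction of valid samples falls
#' below `min_valid_frac` are flagged invalid (their mean, over whatever
#' valid samples exist, is still reported; frames with no valid samples
#' get `NA`).
#'
#' @param series A series tibble with a time column (`time_s`, or
#'   `t_start` for an already-reduced series), a value column
#'   (auto-detected among `ratio`, `omega_hz`, `delta_hz`, `value`), and
#'   optionally `valid`. Reapplying the reduction at the same framing is
#'   the identity.
#' @param w Frame length in seconds, > 0. When `w` exceeds the series
#'   duration a single-frame result is returned with a warning.
#' @param value Name of the value column, if auto-detection is not wanted.
#' @param min_valid_frac Minimum fraction of valid samples for a frame to
#'   count as valid (default 0.5); a flight gap therefore invalidates the
#'   frames it covers rather than being silently averaged over.
#' @return A `paa_series` tibble: `frame`, `t_start`, `t_end`, `value`,
#'   `n_valid`, `valid`; attributes `frame_s` (= `w`) and `n_source`.
#' @examples
#' s <- tibble::tibble(time_s = (0:5), value = c(1, 2, 3, 4, 5, 6))
#' paa_reduce(s, w = 2)$value # frame means 1.5, 3.5, 5.5
#' @export
paa_reduce <- function(series, w, value = NULL, min_valid_frac = 0.5) {
  if (!is.numeric(w) || length(w) != 1 || w <= 0) {
    abort("`w` must be a single positive number of seconds.")
  }
  if (nrow(series) == 0) abort("`series` is empty.")
  vc <- value_col(series, value)
  tc <- time_col(series)
  x <- series[[vc]]
  t <- series[[tc]]
  vld <- valid_of(series)
  n <- length(x)
  fs <- sample_rate(series) %||% 1
  if (inherits(series, "paa_series")) fs <- 1 / attr(series, "frame_s")
  L <- round(w * fs)
  if (L < 1) abort("`w` is shorter than one sample interval.")
  if (L >= n) {
    if (L > n) warn("`w` exceeds the series duration; returning a single frame.")
    L <- n
  }
  frame <- (seq_len(n) - 1L) %/% L + 1L
  N <- max(frame)
  size <- tabulate(frame, N)
  n_valid <- tabulate(frame[vld], N)
  sums <- rep(0, N)
  if (any(vld)) {
    s <- tapply(x[vld], frame[vld], sum)
    sums[as.integer(names(s))] <- as.numeric(s)
  }
  means <- ifelse(n_valid > 0, sums / n_valid, NA_real_)
  t0 <- t[1]
  new_series(
    tibble(frame = seq_len(N),
           t_start = t0 + (seq_len(N) - 1) * L / fs,
           t_end = t0 + pmin(seq_len(N) * L, n) / fs,
           value = means, n_valid = n_valid,
           valid = n_valid / size >= min_valid_frac & n_valid > 0),
    "paa_series", 1 / w, frame_s = w, n_source = n)
}
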
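# Instantaneous-frequency extraction: STFT ridge tracking, time-varying
# band isolation by complex demodulation, phase-derivative IF, smoothing.

#' Tracking-filter specification
#'
#' Parameters of the two-pass fundamental tracker: a coarse short-time
#' Fourier ridge search locates the fundamental inside `search_band_hz`;
#' the signal is then band-limited around the interpolated ridge (half
#' bandwidth `relative_bandwidth` times the tracked frequency) and the
#' instantaneous frequency is read off the analytic-signal phase.
#'
#' Default search bands reflect tethered *Aedes aegypti* fundamentals:
#' males roughly 550--900 Hz, females 350--600 Hz.
#'
#' @param search_band_hz Length-2 numeric, admissible fundamental range
#'   (Hz); may also be `"male"` or `"female"` for the standard bands.
#' @param coarse_window_s Ridge-tracking STFT window (s).
#' @param hop_s STFT hop (s).
#' @param relative_bandwidth Half-width of the tracking pass band as a
#'   fraction of the tracked fundamental, in (0, 0.5).
#' @param if_lowpass_hz Final low-pass cut-off applied to the raw
#'   instantaneous frequency (Hz); wing-beat modulation is far slower
#'   than the audio rate.
#' @param if_median_s Length of the median pre-filter on the raw IF (s).
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(search_band_hz = c(350, 900),
                        coarse_window_s = 0.25, hop_s = 0.05,
                        relative_bandwidth = 0.15,
                        if_lowpass_hz = 50, if_median_s = 0.005) {
  if (is.character(search_band_hz)) {
    search_band_hz <- switch(match.arg(search_band_hz, c("male", "female")),
                             male = c(550, 900), female = c(350, 600))
  }
  if (length(search_band_hz) != 2 || diff(search_band_hz) <= 0 ||
      search_band_hz[1] <= 0) {
    abort("`search_band_hz` must be an increasing positive pair (lo, hi).")
  }
  if (relative_bandwidth <= 0 || relative_bandwidth >= 0.5) {
    abort("`relative_bandwidth` must lie in (0, 0.5).")
  }
  structure(list(search_band_hz = search_band_hz,
                 coarse_window_s = coarse_window_s, hop_s = hop_s,
                 relative_bandwidth = relative_bandwidth,
                 if_lowpass_hz = if_lowpass_hz, if_median_s = if_median_s),
            class = "filter_spec")
}

#' Detect flight-cessation gaps from the amplitude envelope
#'
#' Flags samples whose short-time RMS envelope falls below a fraction of
#' the recording's median envelope for at least `min_gap_s`, marking
#' intervals where the mosquito has stopped flying.
#'
#' @param audio An `audio_rec` tibble.
#' @param envelope_threshold_fraction Gap threshold as a fraction of the
#'   median envelope.
#' @param min_gap_s Minimum gap duration (s); shorter dropouts are
#'   ignored.
#' @param envelope_window_s RMS envelope window (s).
#' @return A logical vector, `TRUE` inside gaps (aligned to the sample
#'   grid). An all-silent recording returns an all-`TRUE` mask with a
#'   warning.
#' @seealso [gap_intervals()]
#' @export
detect_flight_gaps <- function(audio, envelope_threshold_fraction = 0.1,
                               min_gap_s = 0.05, envelope_window_s = 0.01) {
  if (nrow(audio) == 0) abort("Empty recording.")
  fs <- sample_rate(audio)
  x2 <- audio$amplitude^2
  k <- max(1L, round(envelope_window_s * fs))
  cs <- cumsum(c(0, x2))
  lo <- pmax(seq_along(x2) - k %/% 2, 0)
  hi <- pmin(seq_along(x2) + (k - k %/% 2), length(x2))
  env <- sqrt((cs[hi + 1] - cs[lo + 1]) / (hi - lo))
  med <- median(env)
  if (med <= .Machine$double.eps) {
    warn("Recording appears silent; whole record flagged as a flight gap.")
    return(rep(TRUE, nrow(audio)))
  }
  below <- env < envelope_threshold_fraction * med
  # keep only runs of at least min_gap_s
  r <- rle(below)
  r$values <- r$values & (r$lengths >= round(min_gap_s * fs))
  inverse.rle(r)
}

#' Convert a gap mask to intervals
#'
#' @param mask Logical gap mask (from [detect_flight_gaps()]).
#' @param sample_rate_hz Sampling rate of the mask.
#' @return A tibble with columns `start_s`, `end_s`, `duration_s`.
#' @export
gap_intervals <- function(mask, sample_rate_hz) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  tibble(start_s = (starts[keep] - 1) / sample_rate_hz,
         end_s = ends[keep] / sample_rate_hz) |>
    mutate(duration_s = .data$end_s - .data$start_s)
}

stft_ridge <- function(x, fs, spec) {
  L <- round(spec$coarse_window_s * fs)
  H <- max(1L, round(spec$hop_s * fs))
  if (length(x) <= L) abort("Recording is shorter than the tracking window.")
  starts <- seq(1L, length(x) - L + 1L, by = H)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1)) # Hann
  freqs <- (seq_len(L) - 1) * fs / L
  band <- which(freqs >= spec$search_band_hz[1] &
                freqs <= spec$search_band_hz[2])
  if (length(band) < 3) abort("Search band too narrow for the STFT resolution.")
  ridge <- numeric(length(starts))
  peak_ok <- logical(length(starts))
  for (j in seq_along(starts)) {
    seg <- x[starts[j]:(starts[j] + L - 1)] * win
    p <- Mod(fft(seg))[band]^2
    i <- which.max(p)
    peak_ok[j] <- p[i] > 20 * median(p)
    # parabolic interpolation on log power for sub-bin accuracy
    f0 <- freqs[band[i]]
    if (i > 1 && i < length(p) && p[i - 1] > 0 && p[i + 1] > 0) {
      a <- log(p[i - 1]); b <- log(p[i]); c <- log(p[i + 1])
      denom <- a - 2 * b + c
      if (denom < 0) f0 <- f0 + 0.5 * (a - c) / denom * fs / L
    }
    ridge[j] <- f0
  }
  if (!any(peak_ok)) {
    abort("No flight tone: no spectral peak found in the search band.")
  }
  # interpolate across windows that had no clear peak
  if (any(!peak_ok)) {
    ridge[!peak_ok] <- approx(which(peak_ok), ridge[peak_ok],
                              xout = which(!peak_ok), rule = 2)$y
  }
  if (length(ridge) >= 3) ridge <- runmed(ridge, 3)
  list(t = (starts - 1 + L / 2) / fs, f = ridge)
}

#' Track the instantaneous fundamental frequency of a flight tone
#'
#' Two-pass extraction. A coarse short-time Fourier transform tracks the
#' strongest spectral ridge inside the search band; the waveform is then
#' demodulated against the interpolated ridge and low-pass filtered at
#' `relative_bandwidth` times the tracked frequency (a zero-phase
#' Butterworth filter run forward and backward), which isolates the
#' fundamental component as a band-limited analytic signal. The
#' instantaneous frequency is the scaled derivative of its unwrapped
#' phase, median-filtered and low-pass smoothed. Edge zones (half a
#' coarse window at each end and around each flight gap) are marked
#' invalid, as are samples where tracking leaves the search band.
#'
#' @param audio An `audio_rec` tibble (single channel).
#' @param spec A [filter_spec()].
#' @param gap_mask Optional logical gap mask; computed with
#'   [detect_flight_gaps()] defaults when `NULL`.
#' @return A [freq_trace()] at the audio sampling rate.
#' @export
track_fundamental <- function(audio, spec = filter_spec(), gap_mask = NULL) {
  fs <- sample_rate(audio)
  x <- audio$amplitude
  n <- length(x)
  if (is.null(gap_mask)) {
    gap_mask <- tryCatch(detect_flight_gaps(audio),
                         warning = function(w) rep(TRUE, n))
  }
  ridge <- stft_ridge(x, fs, spec)
  fc <- approx(ridge$t, ridge$f, xout = audio$time_s, rule = 2)$y

  # complex demodulation against the ridge: time-varying band isolation
  phi <- 2 * pi * cumsum(fc) / fs
  z <- x * exp(-1i * phi)
  half_bw <- spec$relative_bandwidth * median(fc)
  bf <- signal::butter(4, min(half_bw / (fs / 2), 0.99), type = "low")
  z <- complex(real = signal::filtfilt(bf, Re(z)),
               imaginary = signal::filtfilt(bf, Im(z)))

  dphase <- diff(Arg(z))
  dphase <- (dphase + pi) %% (2 * pi) - pi # unwrap increments
  omega <- fc + c(dphase[1], dphase) * fs / (2 * pi)

  # smooth: short median filter, then low-pass well above wander rates
  k <- round(spec$if_median_s * fs)
  k <- max(3L, k + (k %% 2 == 0))
  omega <- runmed(omega, k)
  lf <- signal::butter(4, min(spec$if_lowpass_hz / (fs / 2), 0.99),
                       type = "low")
  omega <- signal::filtfilt(lf, omega)

  # validity: outside gaps, away from edges/gap borders, inside the band
  valid <- !gap_mask
  edge <- round(spec$coarse_window_s * fs / 2)
  grow <- function(v, m) { # mark m samples around every FALSE run
    if (any(!v)) {
      r <- rle(!v)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
      for (i in which(r$values)) {
        v[max(1L, starts[i] - m):min(length(v), ends[i] + m)] <- FALSE
      }
    }
    v
  }
  valid <- grow(valid, edge)
  valid[seq_len(min(edge, n))] <- FALSE
  valid[seq.int(max(1L, n - edge + 1L), n)] <- FALSE
  valid <- valid & omega >= spec$search_band_hz[1] &
    omega <= spec$search_band_hz[2]

  freq_trace(audio$time_s, pmax(omega, .Machine$double.eps), valid,
             sample_rate_hz = fs, subject = attr(audio, "subject"))
}

#' Harmonic overtone trace
#'
#' Overtones of a flight tone are integer multiples of the fundamental;
#' this scales a fundamental trace to its k-th harmonic, preserving the
#' validity mask.
#'
#' @param trace A [freq_trace()].
#' @param k Positive integer harmonic number (`k = 1` is the identity).
#' @return A [freq_trace()] with `omega_hz` multiplied by `k`.
#' @export
harmonic_trace <- function(trace, k) {
  if (length(k) != 1 || !is_wholenumber(k) || k < 1) {
    abort("`k` must be a single integer >= 1.")
  }
  out <- trace
  out$omega_hz <- trace$omega_hz * k
  out
}
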
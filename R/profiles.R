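#' Flight-tone profile for the synthetic simulator
#'
#' Describes the statistical properties of one mosquito's wing-beat
#' frequency trace: a baseline fundamental frequency, within-recording
#' wander modelled as a mean-reverting (Ornstein--Uhlenbeck style)
#' Gaussian process, and optional flight-cessation gaps.
#'
#' Defaults for the wander dispersion are anchored to published
#' within-recording standard deviations for tethered *Aedes aegypti*
#' (roughly 9--15 Hz). The mean-reversion rate sets the correlation time
#' of the wander (`1/reversion_rate`); its default of 20/s (50 ms) keeps
#' lone-flight traces approximately normally distributed around the
#' baseline while reproducing the rapid sub-second frequency modulation
#' seen in real flight tones, and is calibrated so that non-interacting
#' pairs essentially never dwell a full second inside a +/-1% integer-ratio
#' band (see the package vignette).
#'
#' @param baseline_hz Baseline fundamental frequency (Hz), > 0.
#' @param wander_sd_hz Stationary standard deviation of the
#'   within-recording frequency wander (Hz), >= 0.
#' @param reversion_rate Mean-reversion rate of the wander process (1/s).
#' @param wander_bandwidth_hz Modulation bandwidth of the wander (Hz):
#'   the raw mean-reverting process is low-pass filtered here (and
#'   rescaled to `wander_sd_hz`), reflecting that wing inertia limits how
#'   fast the beat frequency can move.
#' @param gaps Flight-cessation intervals: a data frame with columns
#'   `start_s` and `duration_s`, or `NULL` for none. Gaps must lie within
#'   `[0, duration_s]`.
#' @param duration_s Trace duration in seconds.
#' @param sample_rate_hz Control sampling rate of the frequency trace
#'   (samples/s). Must exceed ten times the baseline Nyquist-wise so the
#'   fifth harmonic of a rendered waveform is representable at the audio
#'   rate implied by the trace; the default 1 kHz control rate is
#'   interpolated up when audio is rendered.
#'
#' @return An object of class `flight_tone_profile`.
#' @seealso [simulate_trace()], [simulate_pair()], [lone_male_profile()]
#' @export
flight_tone_profile <- function(baseline_hz, wander_sd_hz = 10,
                                reversion_rate = 20,
                                wander_bandwidth_hz = 25, gaps = NULL,
                                duration_s = 60, sample_rate_hz = 1000) {
  if (!is.numeric(baseline_hz) || baseline_hz <= 0) {
    abort("`baseline_hz` must be positive.")
  }
  if (!is.numeric(wander_sd_hz) || wander_sd_hz < 0) {
    abort("`wander_sd_hz` must be non-negative.")
  }
  if (!is.numeric(duration_s) || duration_s <= 0) {
    abort("`duration_s` must be positive.")
  }
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0) {
    abort("`sample_rate_hz` must be positive.")
  }
  if (reversion_rate <= 0) abort("`reversion_rate` must be positive.")
  if (!is.null(gaps)) {
    gaps <- as_tibble(gaps)
    stopifnot(all(c("start_s", "duration_s") %in% names(gaps)))
    if (any(gaps$start_s < 0) || any(gaps$duration_s <= 0) ||
        any(gaps$start_s + gaps$duration_s > duration_s + 1e-9)) {
      abort("Gaps must lie within [0, duration_s].")
    }
  }
  structure(
    list(baseline_hz = baseline_hz, wander_sd_hz = wander_sd_hz,
         reversion_rate = reversion_rate,
         wander_bandwidth_hz = wander_bandwidth_hz, gaps = gaps,
         duration_s = duration_s, sample_rate_hz = sample_rate_hz),
    class = "flight_tone_profile")
}

#' Cohort-typical lone-flight profiles
#'
#' Convenience profiles parameterised from published summary statistics
#' of tethered *Aedes aegypti* in lone flight: males at a mean fundamental
#' of 691.2 Hz with within-recording dispersion 11.1 Hz, females at
#' 479.8 Hz with dispersion 9.7 Hz.
#'
#' @param ... Overrides passed on to [flight_tone_profile()].
#' @return A `flight_tone_profile`.
#' @export
lone_male_profile <- function(...) {
  args <- modifyList(list(baseline_hz = 691.2, wander_sd_hz = 11.1), list(...))
  do.call(flight_tone_profile, args)
}

#' @rdname lone_male_profile
#' @export
lone_female_profile <- function(...) {
  args <- modifyList(list(baseline_hz = 479.8, wander_sd_hz = 9.7), list(...))
  do.call(flight_tone_profile, args)
}

#' Script of ground-truth convergence events for the simulator
#'
#' Each row schedules one harmonic-convergence episode during which the
#' steered partner's fundamental is driven so that the pair's frequency
#' ratio approaches the small-integer ratio `p:q` and then holds within
#' `jitter_frac` of it. The approach (and release) ramp spans
#' `3 * ramp_tau_s` seconds, after which containment is guaranteed.
#'
#' @param p,q Integer numerator/denominator of the target ratio, `p >= q >= 1`.
#' @param onset_s Event onsets in seconds (steering start).
#' @param duration_s Event durations in seconds; must exceed `3 * ramp_tau_s`.
#' @param ramp_tau_s Approach time constant (s); the ratio reaches the
#'   target at `onset_s + 3 * ramp_tau_s`.
#' @param jitter_frac Residual relative jitter of the held ratio. Keep it
#'   below the detection tolerance `delta` (default detector uses 0.01).
#'
#' @return A tibble of class `convergence_script`, ordered by onset.
#' @export
convergence_script <- function(p, q, onset_s, duration_s,
                               ramp_tau_s = 0.5, jitter_frac = 0.003) {
  sc <- tibble(p = as.integer(p), q = as.integer(q),
               onset_s = as.numeric(onset_s),
               duration_s = as.numeric(duration_s),
               ramp_tau_s = as.numeric(ramp_tau_s),
               jitter_frac = as.numeric(jitter_frac))
  if (nrow(sc) == 0) {
    class(sc) <- c("convergence_script", class(sc))
    return(sc)
  }
  if (any(sc$p < sc$q) || any(sc$q < 1)) {
    abort("Ratios must satisfy p >= q >= 1.")
  }
  if (any(sc$duration_s <= 3 * sc$ramp_tau_s)) {
    abort("Each event must last longer than its approach ramp (3 * ramp_tau_s).")
  }
  if (any(sc$jitter_frac < 0) || any(sc$jitter_frac >= 1)) {
    abort("`jitter_frac` must lie in [0, 1).")
  }
  sc <- arrange(sc, .data$onset_s)
  # release ramp of one event must not run into the approach of the next
  ends <- sc$onset_s + sc$duration_s + 3 * sc$ramp_tau_s
  if (nrow(sc) > 1 && any(ends[-nrow(sc)] > sc$onset_s[-1])) {
    abort("Scripted events overlap (including approach/release ramps).")
  }
  sc$label <- paste0(sc$p, ":", sc$q)
  class(sc) <- c("convergence_script", class(sc))
  sc
}

#' An empty convergence script
#' @return A zero-row `convergence_script`.
#' @export
empty_script <- function() {
  convergence_script(integer(), integer(), numeric(), numeric())
}
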
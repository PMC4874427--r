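# Synthetic flight-tone generator: seeded OU frequency traces, scripted
# convergence steering for pairs, and harmonic waveform rendering.

ou_wander <- function(n, dt, sd, rate) {
  if (sd == 0 || n == 0) return(numeric(n))
  a <- exp(-rate * dt)
  innov <- rnorm(n, 0, sd * sqrt(1 - a^2))
  x0 <- rnorm(1, 0, sd) # stationary start
  drop(stats::filter(c(x0, innov[-1]), a, method = "recursive"))
}

# band-limited mean-reverting wander: OU innovations low-passed to the
# modulation bandwidth (wing inertia caps how fast the beat frequency can
# move), rescaled to the requested stationary sd
bandlimited_wander <- function(n, dt, sd, rate, bandwidth_hz = 25) {
  x <- ou_wander(n, dt, sd, rate)
  if (sd == 0 || n < 24) return(x)
  w <- 2 * bandwidth_hz * dt
  if (w < 1) {
    bf <- signal::butter(4, w, type = "low")
    x <- signal::filtfilt(bf, x)
    s <- sd(x)
    if (s > 0) x <- x * (sd / s)
  }
  x
}

gap_mask_for <- function(time_s, gaps) {
  valid <- rep(TRUE, length(time_s))
  if (is.null(gaps) || nrow(gaps) == 0) return(valid)
  for (i in seq_len(nrow(gaps))) {
    valid[time_s >= gaps$start_s[i] &
          time_s < gaps$start_s[i] + gaps$duration_s[i]] <- FALSE
  }
  valid
}

#' Simulate a lone flight-tone frequency trace
#'
#' Generates the instantaneous fundamental frequency of one mosquito as
#' `baseline_hz` plus a stationary mean-reverting Gaussian wander,
#' sampled at the profile's control rate. Samples falling inside the
#' profile's flight-cessation gaps are flagged invalid (the frequency
#' value is retained but must not be used).
#'
#' @param profile A [flight_tone_profile()].
#' @param seed Integer seed; identical seeds give identical traces and
#'   the global RNG stream is left untouched.
#' @param subject Optional subject metadata list stored on the trace.
#' @return A [freq_trace()] tibble (`time_s`, `omega_hz`, `valid`).
#' @examples
#' tr <- simulate_trace(lone_female_profile(duration_s = 2), seed = 1)
#' mean(tr$omega_hz)
#' @export
simulate_trace <- function(profile, seed = NULL, subject = NULL) {
  if (!inherits(profile, "flight_tone_profile")) {
    abort("`profile` must be a flight_tone_profile.")
  }
  local_seed(seed)
  fs <- profile$sample_rate_hz
  n <- round(profile$duration_s * fs)
  if (n < 1) abort("Profile duration too short for its sampling rate.")
  t <- (seq_len(n) - 1) / fs
  omega <- profile$baseline_hz +
    bandlimited_wander(n, 1 / fs, profile$wander_sd_hz,
                       profile$reversion_rate, profile$wander_bandwidth_hz)
  freq_trace(t, omega, valid = gap_mask_for(t, profile$gaps),
             sample_rate_hz = fs, subject = subject)
}

# linear steering weight: 0 before onset, 1 on the plateau, ramps of
# length 3*ramp_tau at both ends
steer_weight <- function(t, onset, duration, ramp) {
  up <- pmin(pmax((t - onset) / (3 * ramp), 0), 1)
  down <- pmin(pmax((onset + duration + 3 * ramp - t) / (3 * ramp), 0), 1)
  w <- pmin(up, down)
  w[t < onset | t > onset + duration + 3 * ramp] <- 0
  w
}

#' Simulate an interacting pair with scripted convergence events
#'
#' Both partners evolve as independent lone traces except during scripted
#' events, when the steered partner's fundamental is driven toward the
#' frequency that puts the pair's ratio at the scripted `p:q`. The
#' approach is a linear blend completing at `onset + 3 * ramp_tau_s`;
#' after that the held ratio stays within the event's `jitter_frac` of
#' `p/q` by construction (a clamped mean-reverting residual supplies the
#' imperfection). Steering releases over the same ramp after the event.
#'
#' The returned ground truth records, per event, both the scripted
#' steering interval and the realized in-band interval
#' (`start_s`/`end_s`): the maximal contiguous run around the plateau for
#' which the constructed ratio lies within `band_delta` of `p/q`. The
#' realized interval is the reference for validating event detectors.
#'
#' @param profile_a,profile_b Profiles of the two partners; durations and
#'   control rates must match.
#' @param script A [convergence_script()] (possibly [empty_script()]).
#' @param seed Integer seed.
#' @param steer `"b"` (default), `"a"`, or `"both"`: which partner is
#'   driven during events (both partners share the adjustment when
#'   `"both"`).
#' @param band_delta Reference tolerance used to log realized in-band
#'   intervals in the truth table (matches the detector default of 1%).
#' @return An object of class `synthetic_pair`: a list with elements
#'   `trace_a`, `trace_b` ([freq_trace()]s), `truth` (tibble: `event`,
#'   `p`, `q`, `label`, `onset_s`, `duration_s`, `start_s`, `end_s`) and
#'   `seed`.
#' @examples
#' sc <- convergence_script(3, 2, onset_s = 5, duration_s = 4)
#' pr <- simulate_pair(lone_male_profile(duration_s = 15),
#'                     lone_female_profile(duration_s = 15), sc, seed = 7)
#' pr$truth
#' @export
simulate_pair <- function(profile_a, profile_b, script = empty_script(),
                          seed = NULL, steer = c("b", "a", "both"),
                          band_delta = 0.01) {
  steer <- match.arg(steer)
  if (!inherits(script, "convergence_script")) {
    abort("`script` must be a convergence_script.")
  }
  if (abs(profile_a$duration_s - profile_b$duration_s) > 1e-9 ||
      profile_a$sample_rate_hz != profile_b$sample_rate_hz) {
    abort("Paired profiles must share duration and sampling rate.")
  }
  local_seed(seed)
  tr_a <- simulate_trace(profile_a, seed = NULL,
                         subject = list(id = "a"))
  tr_b <- simulate_trace(profile_b, seed = NULL,
                         subject = list(id = "b"))
  t <- tr_a$time_s
  fs <- profile_a$sample_rate_hz
  omega_a <- tr_a$omega_hz
  omega_b <- tr_b$omega_hz

  if (nrow(script) > 0) {
    a_is_high <- profile_a$baseline_hz >= profile_b$baseline_hz
    for (i in seq_len(nrow(script))) {
      ev <- script[i, ]
      r <- ev$p / ev$q
      # achievability: steered partner must reach the target frequency
      base_hi <- max(profile_a$baseline_hz, profile_b$baseline_hz)
      base_lo <- min(profile_a$baseline_hz, profile_b$baseline_hz)
      reach <- abs(base_hi / r - base_lo) / base_lo
      if (reach > 0.3) {
        abort(sprintf(
          "Event %d (%s) is not achievable: target is %.0f%% away from the partner baseline.",
          i, ev$label, 100 * reach))
      }
      lambda <- steer_weight(t, ev$onset_s, ev$duration_s, ev$ramp_tau_s)
      idx <- lambda > 0
      eps <- ou_wander(sum(idx), 1 / fs, ev$jitter_frac / 3,
                       profile_a$reversion_rate)
      eps <- pmin(pmax(eps, -0.99 * ev$jitter_frac), 0.99 * ev$jitter_frac)
      if (steer == "b") {
        target <- if (a_is_high) omega_a[idx] / r else omega_a[idx] * r
        omega_b[idx] <- (1 - lambda[idx]) * omega_b[idx] +
          lambda[idx] * target * (1 + eps)
      } else if (steer == "a") {
        target <- if (a_is_high) omega_b[idx] * r else omega_b[idx] / r
        omega_a[idx] <- (1 - lambda[idx]) * omega_a[idx] +
          lambda[idx] * target * (1 + eps)
      } else {
        # split the correction evenly in log-frequency
        cur <- pmax(omega_a[idx], omega_b[idx]) / pmin(omega_a[idx], omega_b[idx])
        adj <- sqrt(r * (1 + eps) / cur)
        hi_is_a <- omega_a[idx] >= omega_b[idx]
        fa <- ifelse(hi_is_a, adj, 1 / adj)
        omega_a[idx] <- omega_a[idx] * fa^lambda[idx]
        omega_b[idx] <- omega_b[idx] / fa^lambda[idx]
      }
    }
  }

  trace_a <- freq_trace(t, omega_a, tr_a$valid, fs, subject = list(id = "a"))
  trace_b <- freq_trace(t, omega_b, tr_b$valid, fs, subject = list(id = "b"))

  truth <- script
  if (nrow(script) > 0) {
    r_all <- pmax(omega_a, omega_b) / pmin(omega_a, omega_b)
    starts <- ends <- numeric(nrow(script))
    for (i in seq_len(nrow(script))) {
      ev <- script[i, ]
      inband <- abs(r_all / (ev$p / ev$q) - 1) <= band_delta
      anchor <- which.min(abs(t - (ev$onset_s + 3 * ev$ramp_tau_s)))
      if (!inband[anchor]) { # should not happen by construction
        starts[i] <- ev$onset_s; ends[i] <- ev$onset_s + ev$duration_s
        next
      }
      lo <- anchor
      while (lo > 1 && inband[lo - 1]) lo <- lo - 1
      hi <- anchor
      while (hi < length(t) && inband[hi + 1]) hi <- hi + 1
      starts[i] <- t[lo]; ends[i] <- t[hi] + 1 / fs
    }
    truth <- tibble(event = seq_len(nrow(script)),
                    p = script$p, q = script$q, label = script$label,
                    onset_s = script$onset_s, duration_s = script$duration_s,
                    start_s = starts, end_s = ends)
  } else {
    truth <- tibble(event = integer(), p = integer(), q = integer(),
                    label = character(), onset_s = numeric(),
                    duration_s = numeric(), start_s = numeric(),
                    end_s = numeric())
  }

  structure(list(trace_a = trace_a, trace_b = trace_b, truth = truth,
                 seed = seed),
            class = "synthetic_pair")
}

#' @export
print.synthetic_pair <- function(x, ...) {
  cat(sprintf("# A synthetic flight-tone pair: %.3g s, %d scripted event(s)\n",
              nrow(x$trace_a) / sample_rate(x$trace_a), nrow(x$truth)))
  if (nrow(x$truth)) print(x$truth)
  invisible(x)
}

#' Simulate a cohort of lone recordings
#'
#' Draws per-individual baseline frequencies from a normal population
#' (mean = profile baseline, sd = `sigma_inter_hz`, emulating
#' between-individual spread) and simulates one lone trace per
#' individual.
#'
#' @param n Number of individuals.
#' @param profile Template profile giving the population-mean baseline,
#'   wander and duration.
#' @param sigma_inter_hz Between-individual standard deviation of the
#'   baseline (Hz); 0 gives identical baselines.
#' @param seed Integer seed.
#' @return A list of `n` [freq_trace()]s, names `rec01`, `rec02`, ...
#' @export
simulate_lone_cohort <- function(n, profile, sigma_inter_hz = 0, seed = NULL) {
  local_seed(seed)
  baselines <- rnorm(n, profile$baseline_hz, sigma_inter_hz)
  baselines <- pmax(baselines, 5 * profile$wander_sd_hz + 1)
  ids <- sprintf("rec%02d", seq_len(n))
  out <- lapply(seq_len(n), function(i) {
    p <- profile
    p$baseline_hz <- baselines[i]
    simulate_trace(p, seed = NULL, subject = list(id = ids[i]))
  })
  setNames(out, ids)
}

#' Render a flight-tone waveform from a frequency trace
#'
#' Synthesises audio as a sum of harmonics of the (time-varying)
#' fundamental: `sum_k a_k cos(phase_k(t))` where `phase_k` is the running
#' integral of `2 pi k omega(t)`, plus optional white noise. The control-rate
#' trace is linearly interpolated to the audio rate; samples inside
#' flight gaps render as silence (noise only).
#'
#' @param trace A [freq_trace()].
#' @param harmonic_amplitudes Amplitudes of harmonics 1..K. The default
#'   `1/k` for k = 1..5 mirrors the successively weaker overtones of real
#'   flight tones.
#' @param noise_sd Standard deviation of additive Gaussian noise
#'   (amplitude units; harmonic 1 has amplitude `harmonic_amplitudes[1]`).
#' @param seed Integer seed for the noise.
#' @param sample_rate_hz Audio rate (default 40 kHz). The highest
#'   harmonic must stay below Nyquist.
#' @return An `audio_rec` tibble (`time_s`, `amplitude`) with the audio
#'   rate and the trace's subject as attributes.
#' @export
render_waveform <- function(trace, harmonic_amplitudes = 1 / (1:5),
                            noise_sd = 0, seed = NULL,
                            sample_rate_hz = 40000) {
  if (length(harmonic_amplitudes) < 1) {
    abort("At least one harmonic amplitude is required.")
  }
  K <- length(harmonic_amplitudes)
  if (max(trace$omega_hz) * K >= sample_rate_hz / 2) {
    abort(sprintf(
      "Highest harmonic (%d x %.0f Hz) exceeds the Nyquist frequency %.0f Hz.",
      K, max(trace$omega_hz), sample_rate_hz / 2))
  }
  local_seed(seed)
  fs <- sample_rate_hz
  dur <- nrow(trace) / sample_rate(trace)
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  omega <- approx(trace$time_s, trace$omega_hz, t, rule = 2)$y
  voiced <- approx(trace$time_s, as.numeric(trace$valid), t,
                   method = "constant", f = 0, rule = 2)$y >= 1
  phase1 <- 2 * pi * cumsum(omega) / fs
  wave <- numeric(length(t))
  for (k in seq_len(K)) {
    wave <- wave + harmonic_amplitudes[k] * cos(k * phase1)
  }
  wave[!voiced] <- 0
  if (noise_sd > 0) wave <- wave + rnorm(length(t), 0, noise_sd)
  new_series(tibble(time_s = t, amplitude = wave), "audio_rec", fs,
             subject = attr(trace, "subject"))
}
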
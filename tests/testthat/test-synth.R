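# Synthetic flight-tone generator: traces, scripted pairs, rendering.

test_that("simulate_trace honours the profile and the seeding contract", {
  # zero wander: exactly constant at the baseline
  p0 <- flight_tone_profile(480, wander_sd_hz = 0, duration_s = 2)
  tr0 <- simulate_trace(p0, seed = 1)
  expect_true(all(tr0$omega_hz == 480))
  expect_true(all(tr0$valid))

  # cohort-anchored male profile: 60 s sample SD inside the observed
  # within-recording dispersion range, mean near baseline
  pm <- lone_male_profile(duration_s = 60)
  tr <- simulate_trace(pm, seed = 11)
  expect_gt(sd(tr$omega_hz), 8)
  expect_lt(sd(tr$omega_hz), 15)
  # mean-reverting wander: 60 s mean stays within ~3 standard errors of
  # the baseline (effective sample size set by the 50 ms correlation time)
  expect_lt(abs(mean(tr$omega_hz) - 691.2), 2)

  # seeding: same seed bit-identical, different seeds differ
  expect_identical(simulate_trace(pm, seed = 1), simulate_trace(pm, seed = 1))
  expect_false(isTRUE(all.equal(simulate_trace(pm, seed = 1)$omega_hz,
                                simulate_trace(pm, seed = 2)$omega_hz)))
})

test_that("simulate_trace validates inputs and flags gap samples exactly", {
  expect_error(flight_tone_profile(480, duration_s = -1), "duration")
  expect_error(flight_tone_profile(-5), "baseline")
  expect_error(flight_tone_profile(480, gaps = data.frame(start_s = 5, duration_s = 10),
                                   duration_s = 8), "Gaps")

  gaps <- data.frame(start_s = c(1, 4), duration_s = c(0.5, 1))
  p <- flight_tone_profile(480, wander_sd_hz = 5, gaps = gaps, duration_s = 10)
  tr <- simulate_trace(p, seed = 3)
  # gap conservation: invalid fraction equals total gap time / duration
  expect_identical(mean(!tr$valid), 1.5 / 10)
  expect_true(all(!tr$valid[tr$time_s >= 4 & tr$time_s < 5]))
})

test_that("scripted convergence events steer the pair ratio into band", {
  sc <- convergence_script(3, 2, onset_s = 10, duration_s = 5,
                           ramp_tau_s = 0.5, jitter_frac = 0.003)
  pr <- simulate_pair(lone_male_profile(duration_s = 20),
                      lone_female_profile(duration_s = 20), sc, seed = 5)
  rs <- ratio_series(pr$trace_a, pr$trace_b)
  hold <- rs$time_s > 10 + 3 * 0.5 & rs$time_s < 15
  expect_true(all(rs$ratio[hold] >= 1.5 * (1 - 0.0045)))
  expect_true(all(rs$ratio[hold] <= 1.5 * (1 + 0.0045)))
  # containment at the scripted jitter (construction guarantee)
  expect_true(all(abs(rs$ratio[hold] / 1.5 - 1) <= 0.003))

  # ground truth lists exactly the scripted labels
  sc2 <- convergence_script(c(3, 5), c(2, 3), onset_s = c(5, 20),
                            duration_s = c(5, 5))
  pr2 <- simulate_pair(lone_male_profile(duration_s = 30),
                       lone_female_profile(duration_s = 30), sc2, seed = 9)
  expect_identical(pr2$truth$label, c("3:2", "5:3"))
  expect_identical(tidy(pr2), pr2$truth)
})

test_that("scripts with overlapping or unreachable events are rejected", {
  expect_error(convergence_script(c(3, 3), c(2, 2), onset_s = c(5, 7),
                                  duration_s = c(5, 5)), "overlap")
  expect_error(convergence_script(2, 3, 5, 5), "p >= q")
  # 1:1 would require the female to climb ~44% to the male baseline
  sc <- convergence_script(1, 1, onset_s = 5, duration_s = 5)
  expect_error(simulate_pair(lone_male_profile(duration_s = 20),
                             lone_female_profile(duration_s = 20),
                             sc, seed = 1), "not achievable")
})

test_that("non-interacting pairs essentially never dwell in a ratio band", {
  # Monte-Carlo over seeds: an empty script must give no interval of
  # >= 1 s inside any +/-1% integer-ratio band in at least 95% of runs
  cfg <- detection_config()
  n_events <- vapply(1:25, function(s) {
    pr <- simulate_pair(lone_male_profile(), lone_female_profile(),
                        empty_script(), seed = 6000 + s)
    nrow(detect_events(ratio_series(pr$trace_a, pr$trace_b), cfg))
  }, numeric(1))
  expect_gte(mean(n_events == 0), 0.95)
})

test_that("render_waveform places harmonic peaks where they belong", {
  spec_peak <- function(x, fs, lo, hi) {
    p <- Mod(fft(x))^2
    f <- (seq_along(x) - 1) * fs / length(x)
    sel <- f >= lo & f <= hi
    f[sel][which.max(p[sel])]
  }
  tr <- const_trace(480, duration_s = 2)
  au <- render_waveform(tr, harmonic_amplitudes = 1)
  expect_lt(abs(spec_peak(au$amplitude, 40000, 100, 2000) - 480), 1)

  tr2 <- const_trace(690, duration_s = 2)
  au2 <- render_waveform(tr2, harmonic_amplitudes = c(1, 0.5, 0.25))
  for (k in 1:3) {
    expect_lt(abs(spec_peak(au2$amplitude, 40000, 690 * k - 150,
                            690 * k + 150) - 690 * k), 1)
  }
  # silence in gaps, determinism, Nyquist guard
  gp <- flight_tone_profile(480, wander_sd_hz = 0, duration_s = 2,
                            gaps = data.frame(start_s = 0.5, duration_s = 0.5))
  trg <- simulate_trace(gp, seed = 1)
  aug <- render_waveform(trg, harmonic_amplitudes = 1)
  expect_true(all(aug$amplitude[aug$time_s >= 0.51 & aug$time_s < 0.99] == 0))
  expect_identical(render_waveform(tr, noise_sd = 0.1, seed = 4),
                   render_waveform(tr, noise_sd = 0.1, seed = 4))
  expect_error(render_waveform(const_trace(5000, 1), harmonic_amplitudes = rep(1, 5)),
               "Nyquist")
})

test_that("lone-cohort simulation spreads baselines between individuals", {
  coh <- simulate_lone_cohort(8, lone_male_profile(duration_s = 5),
                              sigma_inter_hz = 90.5, seed = 2)
  expect_length(coh, 8)
  means <- vapply(coh, function(tr) mean(tr$omega_hz), numeric(1))
  expect_gt(sd(means), 20) # clearly larger than within-recording wander
  expect_identical(simulate_lone_cohort(3, lone_female_profile(duration_s = 2),
                                        30, seed = 7),
                   simulate_lone_cohort(3, lone_female_profile(duration_s = 2),
                                        30, seed = 7))
})
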
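# PAA reduction, tolerance bands, event detection, cohort summaries.

test_that("paa_reduce computes frame means per the reduction formula", {
  s4 <- tibble::tibble(time_s = 0:3, value = c(5, 5, 5, 5))
  expect_equal(paa_reduce(s4, w = 2)$value, c(5, 5))
  s6 <- tibble::tibble(time_s = 0:5, value = 1:6)
  expect_equal(paa_reduce(s6, w = 2)$value, c(1.5, 3.5, 5.5))

  # seeded noisy sine vs brute-force frame-mean oracle, machine precision
  set.seed(42)
  n <- 20000
  t <- (seq_len(n) - 1) / 1000
  clean <- sin(2 * pi * 0.2 * t)
  x <- clean + rnorm(n, 0, 0.5)
  s <- tibble::tibble(time_s = t, value = x)
  w <- n / 40 / 1000 # 40 frames
  red <- paa_reduce(s, w = w)
  expect_equal(nrow(red), 40)
  expect_equal(red$value, paa_oracle(x, rep(TRUE, n), n / 40), tolerance = 1e-12)
  # noise suppression: reduced series tracks the clean sine
  clean_red <- paa_oracle(clean, rep(TRUE, n), n / 40)
  rmse <- sqrt(mean((red$value - clean_red)^2))
  expect_lt(rmse, 0.5 / sqrt(n / 40) * 1.5)
})

test_that("paa_reduce conserves means, is idempotent, keeps partial frames", {
  s <- tibble::tibble(time_s = (0:99) / 10, value = rnorm(100))
  red <- paa_reduce(s, w = 1) # 10 frames of 10
  expect_equal(mean(red$value), mean(s$value), tolerance = 1e-12)
  red2 <- paa_reduce(red, w = 1)
  expect_equal(red2$value, red$value)
  expect_equal(red2$t_start, red$t_start)

  # trailing partial frame averaged over what it has
  s2 <- tibble::tibble(time_s = 0:6, value = c(1, 1, 2, 2, 3, 3, 9))
  r2 <- paa_reduce(s2, w = 2)
  expect_equal(r2$value, c(1, 2, 3, 9))

  # frames with under half their samples valid are flagged invalid
  s3 <- tibble::tibble(time_s = (0:19) / 10, value = rep(1, 20),
                       valid = rep(c(TRUE, FALSE), c(12, 8)))
  r3 <- paa_reduce(s3, w = 1)
  expect_identical(r3$valid, c(TRUE, FALSE))
  expect_identical(r3$n_valid, c(10L, 2L))

  expect_warning(paa_reduce(s2, w = 100), "single frame")
  expect_error(paa_reduce(s2, w = -1), "w")
})

test_that("tolerance bands are the delta-interval around p/q", {
  b <- tolerance_band(3, 2, 0.01)
  expect_identical(b$lo, 1.5 * 0.99)
  expect_identical(b$hi, 1.5 * 1.01)
  expect_equal(c(b$lo, b$hi), c(1.485, 1.515))
  expect_equal(unlist(tolerance_band(1, 1, 0.01)[, c("lo", "hi")]),
               c(lo = 0.99, hi = 1.01))
  expect_equal(unlist(tolerance_band(2, 1, 0.02)[, c("lo", "hi")]),
               c(lo = 1.96, hi = 2.04))
  expect_error(tolerance_band(2, 3, 0.01), "p >= q")
  expect_error(tolerance_band(3, 2, 1.5), "delta")
})

test_that("detection_config rejects overlapping bands", {
  expect_error(detection_config(delta = 0.04,
                                ratios = tibble::tibble(p = c(5, 4),
                                                        q = c(4, 3))),
               "overlap")
  cfg <- detection_config()
  expect_equal(nrow(cfg$bands), 6)
})

test_that("detect_events applies duration and separation rules", {
  fs <- 1000
  mk_ratio <- function(vals_per_sec) {
    n <- length(vals_per_sec) * fs
    r <- rep(vals_per_sec, each = fs)
    flighttones:::new_series(
      tibble::tibble(time_s = (seq_len(n) - 1) / fs, ratio = r,
                     valid = TRUE), "ratio_series", fs)
  }
  cfg <- detection_config()

  # constant 1.50 for 10 s: one 3:2 event covering the record
  ev <- detect_events(mk_ratio(rep(1.5, 10)), cfg)
  expect_equal(nrow(ev), 1)
  expect_identical(ev$label, "3:2")
  expect_equal(ev$duration_s, 10, tolerance = 0.51)

  # 0.8 s in band is under tau = 1 s: no event
  r2 <- c(rep(1.3, 5 * fs), rep(1.5, 0.8 * fs), rep(1.3, 5 * fs))
  rs2 <- flighttones:::new_series(
    tibble::tibble(time_s = (seq_along(r2) - 1) / fs, ratio = r2,
                   valid = TRUE), "ratio_series", fs)
  expect_equal(nrow(detect_events(rs2, cfg)), 0)

  # two 2-s runs bridged by a 0.5-s excursion merge into one event
  r3 <- c(rep(1.3, 2 * fs), rep(1.5, 2 * fs), rep(1.3, 0.5 * fs),
          rep(1.5, 2 * fs), rep(1.3, 2 * fs))
  rs3 <- flighttones:::new_series(
    tibble::tibble(time_s = (seq_along(r3) - 1) / fs, ratio = r3,
                   valid = TRUE), "ratio_series", fs)
  ev3 <- detect_events(rs3, cfg)
  expect_equal(nrow(ev3), 1)
  expect_equal(ev3$duration_s, 4.5, tolerance = 0.51)
  # with gap handling "discard" the two runs stay separate
  ev3d <- detect_events(rs3, detection_config(gap_handling = "discard"))
  expect_equal(nrow(ev3d), 2)

  # an invalid frame inside the gap must not be bridged
  rs4 <- rs3
  rs4$valid[rs4$time_s >= 4.1 & rs4$time_s < 4.4] <- FALSE
  ev4 <- detect_events(rs4, cfg)
  expect_equal(nrow(ev4), 2)
})

test_that("detect_events matches a brute-force run scan on random instances", {
  fs <- 100
  cfg <- detection_config()
  set.seed(7)
  for (trial in 1:100) {
    # random frame-level ratio values: mostly background, some in-band
    n_frames <- sample(10:60, 1)
    band_i <- sample(nrow(cfg$bands), n_frames, replace = TRUE)
    in_band <- runif(n_frames) < 0.35
    vals <- ifelse(in_band,
                   cfg$bands$ratio[band_i] * (1 + runif(n_frames, -0.009, 0.009)),
                   runif(n_frames, 1.02, 1.2))
    frame_valid <- runif(n_frames) > 0.1
    r <- rep(vals, each = fs * 0.5)
    v <- rep(frame_valid, each = fs * 0.5)
    rs <- flighttones:::new_series(
      tibble::tibble(time_s = (seq_along(r) - 1) / fs, ratio = r, valid = v),
      "ratio_series", fs)
    got <- detect_events(rs, cfg)
    want <- dplyr::bind_rows(lapply(seq_len(nrow(cfg$bands)), function(bi) {
      state <- frame_valid & vals >= cfg$bands$lo[bi] & vals <= cfg$bands$hi[bi]
      runs <- event_scan_oracle(state, frame_valid, 0.5, 1, 1)
      if (!length(runs)) return(NULL)
      tibble::tibble(label = cfg$bands$label[bi],
                     start_s = vapply(runs, function(x) (x[1] - 1) * 0.5, 1),
                     end_s = vapply(runs, function(x) x[2] * 0.5, 1))
    }))
    got <- got[order(got$start_s, got$label), c("label", "start_s", "end_s")]
    if (is.null(want) || nrow(want) == 0) {
      expect_equal(nrow(got), 0)
    } else {
      want <- want[order(want$start_s, want$label), ]
      expect_equal(as.data.frame(got), as.data.frame(want),
                   ignore_attr = TRUE)
    }
  }
})

test_that("detection is monotone in delta and tau", {
  pr <- simulate_pair(lone_male_profile(duration_s = 40),
                      lone_female_profile(duration_s = 40),
                      convergence_script(3, 2, 10, 8, jitter_frac = 0.008),
                      seed = 21)
  rs <- ratio_series(pr$trace_a, pr$trace_b)
  conv_time <- vapply(c(0.002, 0.005, 0.01, 0.02), function(d) {
    sum(detect_events(rs, detection_config(delta = d))$duration_s)
  }, numeric(1))
  expect_true(all(diff(conv_time) >= 0))
  counts <- vapply(c(0.5, 1, 2, 5, 10), function(tau) {
    nrow(detect_events(rs, detection_config(tau = tau)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("scripted events are recovered with matching labels and bounds", {
  sc <- convergence_script(c(3, 5, 2), c(2, 3, 1),
                           onset_s = c(5, 10, 16), duration_s = c(3, 4, 3))
  pr <- simulate_pair(lone_male_profile(duration_s = 22),
                      lone_female_profile(duration_s = 22), sc, seed = 33)
  rs <- ratio_series(pr$trace_a, pr$trace_b)
  ev <- detect_events(rs, detection_config())
  expect_equal(nrow(ev), 3)
  m <- match_events(ev, pr$truth)
  expect_true(all(!is.na(m$boundary_err)))
  expect_true(all(m$boundary_err <= 0.5))
  expect_equal(m$n_false, 0)
  # event invariants: duration >= tau, same-label events separated > delta_tau
  expect_true(all(ev$duration_s >= 1))
})

test_that("event_samples returns the in-event full-resolution data", {
  pr <- simulate_pair(lone_male_profile(duration_s = 15),
                      lone_female_profile(duration_s = 15),
                      convergence_script(3, 2, 5, 5), seed = 2)
  rs <- ratio_series(pr$trace_a, pr$trace_b)
  ev <- detect_events(rs, detection_config())
  smp <- event_samples(rs, ev)
  expect_true(all(smp$time_s >= ev$start_s[1] & smp$time_s < ev$end_s[1]))
  expect_equal(nrow(smp), sum(rs$valid & rs$time_s >= ev$start_s[1] &
                                rs$time_s < ev$end_s[1]))
})

test_that("summarize_cohort reproduces the standard rate arithmetic", {
  # 39 events over 30 recordings from 18 unique pairs
  recs <- tibble::tibble(recording_id = sprintf("r%02d", 1:30),
                         pair_id = sprintf("p%02d", c(1:18, 1:12)))
  ev <- tibble::tibble(recording_id = sample(recs$recording_id[1:14], 39,
                                             replace = TRUE),
                       label = "1:1")
  s <- summarize_cohort(ev, recs)
  expect_equal(s$events_per_recording, 1.3)
  expect_equal(s$events_per_pair, round(39 / 18, 1))
  expect_equal(s$recordings_total, 30)

  # per-recording rate for 111 events over 43 recordings
  recs2 <- tibble::tibble(recording_id = as.character(1:43),
                          pair_id = as.character(c(1:24, 1:19)))
  ev2 <- tibble::tibble(recording_id = rep("1", 111), label = "3:2")
  expect_equal(summarize_cohort(ev2, recs2)$events_per_recording, 2.6)

  # no events: all-zero summary
  s0 <- summarize_cohort(NULL, recs)
  expect_equal(s0$events_total, 0)
  expect_equal(s0$pct_with_event, 0)
  expect_equal(s0$events_per_recording, 0)
})

test_that("aggregate_durations sums per recording and excludes empty ones", {
  ev <- tibble::tibble(recording_id = c("a", "a", "b"),
                       duration_s = c(2, 3, 1.5))
  agg <- aggregate_durations(ev)
  expect_equal(agg$gamma_s[agg$recording_id == "a"], 5)
  expect_false("c" %in% agg$recording_id)
  recs <- tibble::tibble(recording_id = c("a", "b", "c"))
  agg2 <- aggregate_durations(ev, recs, keep_empty = TRUE)
  expect_equal(agg2$gamma_s[agg2$recording_id == "c"], 0)
})

test_that("scripted duration distributions are recovered from simulation", {
  set.seed(5)
  durs <- runif(12, 2, 6)
  events <- lapply(seq_along(durs), function(i) {
    sc <- convergence_script(3, 2, onset_s = 5, duration_s = durs[i])
    pr <- simulate_pair(lone_male_profile(duration_s = 16),
                        lone_female_profile(duration_s = 16), sc,
                        seed = 500 + i)
    ev <- detect_events(ratio_series(pr$trace_a, pr$trace_b),
                        detection_config())
    ev$recording_id <- sprintf("r%02d", i)
    ev
  })
  all_ev <- dplyr::bind_rows(events)
  st <- duration_stats(all_ev)
  # recovered mean within 2 standard errors of the scripted mean
  expect_lt(abs(st$mean_s - mean(durs)), 2 * st$se_s + 0.5)
  g <- glance(events[[1]])
  expect_equal(g$n_events, nrow(events[[1]]))
  expect_equal(g$total_convergence_s, sum(events[[1]]$duration_s))
})
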
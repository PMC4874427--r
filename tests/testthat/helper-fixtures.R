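# Fixtures are generated in code: constant/chirp traces, short profiles,
# and independent brute-force oracles used to cross-check the package's
# vectorised implementations.

const_trace <- function(f, duration_s = 10, fs = 1000, valid = TRUE) {
  n <- round(duration_s * fs)
  freq_trace((seq_len(n) - 1) / fs, rep(f, n), valid = valid,
             sample_rate_hz = fs)
}

chirp_trace <- function(f0, f1, duration_s = 10, fs = 1000) {
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  freq_trace(t, f0 + (f1 - f0) * t / duration_s, sample_rate_hz = fs)
}

short_male <- function(duration_s = 10, ...) {
  lone_male_profile(duration_s = duration_s, ...)
}

short_female <- function(duration_s = 10, ...) {
  lone_female_profile(duration_s = duration_s, ...)
}

# brute-force per-frame mean (PAA oracle): plain loop, no tapply
paa_oracle <- function(x, valid, L) {
  N <- ceiling(length(x) / L)
  means <- numeric(N)
  for (i in seq_len(N)) {
    idx <- ((i - 1) * L + 1):min(i * L, length(x))
    v <- x[idx][valid[idx]]
    means[i] <- if (length(v)) sum(v) / length(v) else NA_real_
  }
  means
}

# brute-force event scan over a binary frame-state vector:
# merge in-state runs separated by <= dtau of all-valid gap, then keep
# runs spanning >= tau
event_scan_oracle <- function(state, frame_valid, w, tau, dtau,
                              merge = TRUE) {
  n <- length(state)
  runs <- list()
  i <- 1
  while (i <= n) {
    if (state[i]) {
      j <- i
      while (j < n && state[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  if (merge && length(runs) > 1) {
    merged <- list(runs[[1]])
    for (k in 2:length(runs)) {
      prev <- merged[[length(merged)]]
      gap <- (runs[[k]][1] - prev[2] - 1)
      gap_idx <- if (gap > 0) (prev[2] + 1):(runs[[k]][1] - 1) else integer()
      if (gap * w <= dtau && all(frame_valid[gap_idx])) {
        merged[[length(merged)]] <- c(prev[1], runs[[k]][2])
      } else {
        merged[[length(merged) + 1]] <- runs[[k]]
      }
    }
    runs <- merged
  }
  keep <- vapply(runs, function(r) (r[2] - r[1] + 1) * w >= tau, logical(1))
  runs[keep]
}

# windowed sd/mean oracle for the local coefficient of variation
cv_oracle <- function(x, k) {
  n <- length(x)
  h <- (k - 1) %/% 2
  out <- rep(NA_real_, n)
  for (i in (h + 1):(n - h)) {
    win <- x[(i - h):(i + h)]
    out[i] <- stats::sd(win) / mean(win)
  }
  out
}

# match detected events to ground-truth intervals by label + overlap;
# returns per-truth-event boundary error (NA if unmatched) and the count
# of detected events that match no truth interval
match_events <- function(detected, truth) {
  used <- rep(FALSE, nrow(detected))
  err <- rep(NA_real_, nrow(truth))
  for (i in seq_len(nrow(truth))) {
    for (j in seq_len(nrow(detected))) {
      if (used[j]) next
      if (detected$label[j] != truth$label[i]) next
      if (detected$start_s[j] < truth$end_s[i] &&
          detected$end_s[j] > truth$start_s[i]) {
        err[i] <- max(abs(detected$start_s[j] - truth$start_s[i]),
                      abs(detected$end_s[j] - truth$end_s[i]))
        used[j] <- TRUE
        break
      }
    }
  }
  list(boundary_err = err, n_false = sum(!used))
}
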
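# Pairwise ratio and separation series, cohort distributions, and the
# randomized non-interacting ("artificial pair") null.

check_pairable <- function(a, b) {
  fa <- sample_rate(a); fb <- sample_rate(b)
  if (!isTRUE(all.equal(fa, fb, tolerance = 1e-6))) {
    abort("Traces must share a sampling rate.")
  }
  list(n = min(nrow(a), nrow(b)), fs = fa)
}

#' Instantaneous frequency-ratio series of a pair
#'
#' The instantaneous ratio of two fundamental traces, taken per sample
#' with the lower frequency as the denominator, so `r(t) >= 1` always and
#' 1:1 convergence is representable even when the traces cross. The
#' result is symmetric in its arguments and is valid only where both
#' traces are.
#'
#' @param a,b [freq_trace()]s with equal sampling rates; truncated to
#'   their common support.
#' @return A `ratio_series` tibble (`time_s`, `ratio`, `valid`).
#' @export
ratio_series <- function(a, b) {
  cp <- check_pairable(a, b)
  a <- a[seq_len(cp$n), ]; b <- b[seq_len(cp$n), ]
  valid <- a$valid & b$valid
  if (any(valid & (a$omega_hz <= 0 | b$omega_hz <= 0))) {
    abort("Non-positive frequency at a valid sample.")
  }
  r <- pmax(a$omega_hz, b$omega_hz) / pmin(a$omega_hz, b$omega_hz)
  new_series(tibble(time_s = a$time_s, ratio = r, valid = valid),
             "ratio_series", cp$fs)
}

#' Instantaneous frequency-separation series of a pair
#'
#' Absolute difference `|f_a - f_b|` between two fundamental traces, per
#' jointly valid sample. Male--male interactions play out at the
#' fundamental, where the separation (rather than the ratio) exposes the
#' near-convergent versus divergent states.
#'
#' @inheritParams ratio_series
#' @return A `separation_series` tibble (`time_s`, `delta_hz`, `valid`).
#' @export
separation_series <- function(a, b) {
  cp <- check_pairable(a, b)
  a <- a[seq_len(cp$n), ]; b <- b[seq_len(cp$n), ]
  valid <- a$valid & b$valid
  if (any(valid & (a$omega_hz <= 0 | b$omega_hz <= 0))) {
    abort("Non-positive frequency at a valid sample.")
  }
  new_series(tibble(time_s = a$time_s,
                    delta_hz = abs(a$omega_hz - b$omega_hz),
                    valid = valid),
             "separation_series", cp$fs)
}

#' Pooled cohort distribution of a pairwise series
#'
#' Histograms the valid samples of many pairs' ratio (or separation)
#' series on a common grid and returns a density-normalized
#' distribution. With `weighting = "equal-pair"` (default) each pair's
#' own density contributes equally, so long recordings do not dominate;
#' `"pooled"` lumps all samples together.
#'
#' @param pairs A list of `ratio_series` (or `separation_series`).
#' @param bin_width Histogram bin width (ratio units, default 0.005; use
#'   e.g. 1 Hz for separations).
#' @param weighting `"equal-pair"` or `"pooled"`.
#' @return A `cohort_distribution` tibble (`bin_left`, `bin_right`,
#'   `density`) whose density integrates to 1; attributes `n_pairs` and
#'   `total_valid_s`.
#' @export
cohort_ratio_distribution <- function(pairs, bin_width = 0.005,
                                      weighting = c("equal-pair", "pooled")) {
  weighting <- match.arg(weighting)
  if (is.data.frame(pairs)) pairs <- list(pairs)
  vals <- lapply(pairs, function(p) p[[value_col(p)]][valid_of(p)])
  keep <- lengths(vals) > 0
  if (!any(keep)) abort("No valid samples in any pair.")
  vals <- vals[keep]
  total_s <- sum(vapply(seq_along(pairs)[keep], function(i) {
    sum(valid_of(pairs[[i]])) / sample_rate(pairs[[i]])
  }, numeric(1)))
  rng <- range(unlist(vals))
  edges <- seq(floor(rng[1] / bin_width) * bin_width,
               ceiling(rng[2] / bin_width + 1e-9) * bin_width + bin_width,
               by = bin_width)
  counts <- vapply(vals, function(v) {
    tabulate(findInterval(v, edges, rightmost.closed = FALSE),
             nbins = length(edges) - 1)
  }, numeric(length(edges) - 1))
  counts <- matrix(counts, nrow = length(edges) - 1)
  dens <- if (weighting == "equal-pair") {
    per_pair <- sweep(counts, 2, colSums(counts), "/")
    rowMeans(per_pair) / bin_width
  } else {
    rowSums(counts) / sum(counts) / bin_width
  }
  new_series(tibble(bin_left = edges[-length(edges)],
                    bin_right = edges[-1], density = dens),
             "cohort_distribution", NA_real_,
             n_pairs = length(vals), total_valid_s = total_s,
             weighting = weighting, bin_width = bin_width)
}

#' Randomized non-interacting pairs from lone recordings
#'
#' Builds the "artificial pair" null cohort: lone recordings of the two
#' groups are cross-combined at random into pairs that cannot have
#' interacted, yet can be subjected to the same ratio and event analysis
#' as live pairs. Drawn uniformly without replacement from the full
#' cross product, so all `count` index pairs are distinct.
#'
#' @param lone_a,lone_b Lists of lone [freq_trace()]s.
#' @param count Number of pairs to draw; at most
#'   `length(lone_a) * length(lone_b)`.
#' @param seed Integer seed (same seed, same pairing).
#' @return A tibble with columns `idx_a`, `idx_b` and list-columns
#'   `trace_a`, `trace_b` (each pair truncated to the common duration).
#' @export
make_artificial_pairs <- function(lone_a, lone_b, count, seed = NULL) {
  na <- length(lone_a); nb <- length(lone_b)
  if (count > na * nb) {
    abort(sprintf("`count` (%d) exceeds the number of distinct cross pairs (%d).",
                  count, na * nb))
  }
  local_seed(seed)
  k <- sample.int(na * nb, count)
  idx_a <- (k - 1L) %/% nb + 1L
  idx_b <- (k - 1L) %% nb + 1L
  pairs <- purrr::map2(idx_a, idx_b, function(i, j) {
    n <- min(nrow(lone_a[[i]]), nrow(lone_b[[j]]))
    list(a = lone_a[[i]][seq_len(n), ], b = lone_b[[j]][seq_len(n), ])
  })
  tibble(idx_a = idx_a, idx_b = idx_b,
         trace_a = purrr::map(pairs, "a"),
         trace_b = purrr::map(pairs, "b"))
}
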
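# Convergence-event detection: tolerance bands around integer ratios,
# PAA binary in-band states, run merging and duration thresholding.

#' Tolerance band around an integer ratio
#'
#' The interval `(p/q) * (1 -/+ delta)` within which a frequency ratio is
#' considered convergent at `p:q`. For 3:2 at `delta = 0.01` this is
#' `[1.485, 1.515]`.
#'
#' @param p,q Integer numerator/denominator (vectorised), `p >= q >= 1`.
#' @param delta Relative tolerance in (0, 1).
#' @return A tibble with columns `label`, `p`, `q`, `ratio`, `lo`, `hi`.
#' @examples
#' tolerance_band(3, 2, 0.01)
#' @export
tolerance_band <- function(p, q = 1, delta = 0.01) {
  if (length(delta) != 1 || !is.numeric(delta) || delta <= 0 || delta >= 1) {
    abort("`delta` must be a single number in (0, 1).")
  }
  if (length(p) != length(q) && length(q) != 1) {
    abort("`p` and `q` must have matching lengths.")
  }
  q <- rep_len(q, length(p))
  if (any(!is_wholenumber(p)) || any(!is_wholenumber(q)) ||
      any(p < q) || any(q < 1)) {
    abort("Ratios must be integers with p >= q >= 1.")
  }
  r <- p / q
  tibble(label = paste0(p, ":", q), p = as.integer(p), q = as.integer(q),
         ratio = r, lo = r * (1 - delta), hi = r * (1 + delta))
}

#' Standard convergence ratio sets
#'
#' Integer ratios at which harmonic convergence is searched for:
#' male--female pairs use 1:1, 5:4, 4:3, 3:2, 5:3 and 2:1 (the ratios at
#' which opposite-sex convergence has been identified; 7:6 is excluded by
#' default because harmonics that high carry little acoustic energy, but
#' can be added via `extra`); male--male pairs interact at the
#' fundamental, 1:1 only.
#'
#' @param extra Optional data frame with integer columns `p`, `q` of
#'   additional ratios.
#' @return A tibble with columns `p`, `q`.
#' @export
mf_ratio_set <- function(extra = NULL) {
  rs <- tibble(p = c(1L, 5L, 4L, 3L, 5L, 2L), q = c(1L, 4L, 3L, 2L, 3L, 1L))
  if (!is.null(extra)) rs <- bind_rows(rs, as_tibble(extra)[c("p", "q")])
  rs
}

#' @rdname mf_ratio_set
#' @export
mm_ratio_set <- function() tibble(p = 1L, q = 1L)

#' Detection configuration
#'
#' Parameters of the convergence-event detector: PAA window `w`, in-band
#' tolerance `delta`, minimum event duration `tau`, and minimum
#' separation `delta_tau` between distinct events. The defaults
#' (`w = 0.5` s, `delta = 0.01`, `tau = 1` s, `delta_tau = 1` s) detect
#' convergence events robustly in tethered-pair recordings.
#'
#' Tolerance bands of all configured ratios must be pairwise disjoint at
#' the chosen `delta`; overlapping configurations are rejected rather
#' than tie-broken, so every event has a unique ratio label.
#'
#' @param w PAA frame length (s).
#' @param delta Relative in-band tolerance.
#' @param tau Minimum event duration (s).
#' @param delta_tau Minimum separation between events (s); in-band runs
#'   separated by no more than this are handled per `gap_handling`.
#' @param ratios Data frame of integer ratio targets (columns `p`, `q`);
#'   default [mf_ratio_set()].
#' @param min_valid_frac Passed to [paa_reduce()]; frames with fewer
#'   valid samples are treated as out of band and count toward event
#'   separation, so a flight gap never silently bridges an event.
#' @param gap_handling `"merge"` (default): short sub-`delta_tau`
#'   excursions between in-band runs are absorbed into one event before
#'   the `tau` threshold is applied; `"discard"`: runs stand alone.
#'   Gaps containing invalid frames are never merged across.
#' @return A list of class `detection_config` (with a `bands` tibble).
#' @export
detection_config <- function(w = 0.5, delta = 0.01, tau = 1, delta_tau = 1,
                             ratios = mf_ratio_set(), min_valid_frac = 0.5,
                             gap_handling = c("merge", "discard")) {
  gap_handling <- match.arg(gap_handling)
  if (w <= 0 || tau <= 0 || delta_tau <= 0) {
    abort("`w`, `tau` and `delta_tau` must be positive.")
  }
  bands <- tolerance_band(ratios$p, ratios$q, delta)
  bands <- arrange(bands, .data$ratio)
  if (nrow(bands) > 1 && any(bands$hi[-nrow(bands)] >= bands$lo[-1])) {
    abort("Tolerance bands overlap at this `delta`; choose disjoint ratios or a smaller tolerance.")
  }
  structure(list(w = w, delta = delta, tau = tau, delta_tau = delta_tau,
                 bands = bands, min_valid_frac = min_valid_frac,
                 gap_handling = gap_handling),
            class = "detection_config")
}

#' @export
print.detection_config <- function(x, ...) {
  cat(sprintf("# Convergence detection: w=%g s, delta=%g, tau=%g s, delta_tau=%g s (%s)\n",
              x$w, x$delta, x$tau, x$delta_tau, x$gap_handling))
  cat("# ratios:", paste(x$bands$label, collapse = ", "), "\n")
  invisible(x)
}

# frame-state run segmentation for one band; returns frame index runs
segment_runs <- function(state, frame_valid, w, tau, delta_tau, merge_gaps) {
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  if (merge_gaps && length(r$values) > 2) {
    for (i in seq(2, length(r$values) - 1)) {
      if (!r$values[i] && r$values[i - 1] && r$values[i + 1] &&
          r$lengths[i] * w <= delta_tau &&
          all(frame_valid[starts[i]:ends[i]])) {
        r$values[i] <- TRUE
      }
    }
    merged <- inverse.rle(r)
    r <- rle(merged)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
  }
  keep <- r$values & r$lengths * w >= tau
  tibble(first = starts[keep], last = ends[keep])
}

#' Detect harmonic-convergence events in a ratio series
#'
#' Implements frame-based event segmentation: (1) the ratio series is
#' PAA-reduced with window `w`; (2) each frame gets a binary in-band
#' state per target ratio (invalid frames are out of band); (3) in-band
#' runs separated by gaps of at most `delta_tau` are merged (unless the
#' gap includes an invalid frame, or `gap_handling = "discard"`); (4)
#' merged runs shorter than `tau` are dropped. Event boundaries have
#' frame resolution; reported events of one ratio are separated by more
#' than `delta_tau`, and bands are disjoint so each event carries exactly
#' one label. Use [event_samples()] to recover the full-resolution ratio
#' samples inside the detected bounds for downstream analysis.
#'
#' @param ratio A `ratio_series` (from [ratio_series()]).
#' @param config A [detection_config()].
#' @return A `convergence_events` tibble: `label`, `p`, `q`, `start_s`,
#'   `end_s`, `duration_s`, ordered by start time, with the
#'   configuration attached as attribute `config`. Event intervals are
#'   half-open `[start_s, end_s)`.
#' @examples
#' tr_m <- freq_trace(0:9999 / 1000, rep(690, 10000), sample_rate_hz = 1000)
#' tr_f <- freq_trace(0:9999 / 1000, rep(460, 10000), sample_rate_hz = 1000)
#' detect_events(ratio_series(tr_m, tr_f), detection_config())
#' @export
detect_events <- function(ratio, config = detection_config()) {
  if (!inherits(config, "detection_config")) {
    abort("`config` must be a detection_config.")
  }
  paa <- paa_reduce(ratio, config$w, value = "ratio",
                    min_valid_frac = config$min_valid_frac)
  out <- purrr::pmap(config$bands, function(label, p, q, ratio, lo, hi) {
    state <- paa$valid & !is.na(paa$value) & paa$value >= lo & paa$value <= hi
    runs <- segment_runs(state, paa$valid, config$w, config$tau,
                         config$delta_tau,
                         merge_gaps = config$gap_handling == "merge")
    if (nrow(runs) == 0) return(NULL)
    tibble(label = label, p = p, q = q,
           start_s = paa$t_start[runs$first],
           end_s = paa$t_end[runs$last])
  })
  ev <- bind_rows(out)
  if (nrow(ev) == 0) {
    ev <- tibble(label = character(), p = integer(), q = integer(),
                 start_s = numeric(), end_s = numeric())
  }
  ev <- ev |>
    mutate(duration_s = .data$end_s - .data$start_s) |>
    arrange(.data$start_s, .data$label)
  attr(ev, "config") <- config
  class(ev) <- c("convergence_events", class(tibble()))
  ev
}

#' Full-resolution samples inside detected events
#'
#' After frame-level detection, downstream metrics use the original
#' full-resolution ratio data restricted to the event bounds.
#'
#' @param ratio The `ratio_series` the events were detected in.
#' @param events A `convergence_events` tibble.
#' @return A tibble of the valid ratio samples inside each event, with
#'   `event` (row index into `events`) and `label` columns.
#' @export
event_samples <- function(ratio, events) {
  if (nrow(events) == 0) {
    return(tibble(event = integer(), label = character(),
                  time_s = numeric(), ratio = numeric()))
  }
  purrr::map_dfr(seq_len(nrow(events)), function(i) {
    sel <- ratio$time_s >= events$start_s[i] &
      ratio$time_s < events$end_s[i] & ratio$valid
    tibble(event = i, label = events$label[i],
           time_s = ratio$time_s[sel], ratio = ratio$ratio[sel])
  })
}
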
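# File formats and the end-to-end pipeline.
#
# All CSV products are UTF-8 with a header row and '.' decimal; times in
# seconds from recording start, frequencies in Hz; event intervals are
# half-open [start_s, end_s).

#' Read and write frequency-trace CSV files
#'
#' Traces are exchanged as CSV with columns `time_s`, `omega_hz`,
#' `valid` (0/1).
#'
#' @param trace A [freq_trace()].
#' @param path File path.
#' @return `write_trace_csv` returns `path` invisibly; `read_trace_csv`
#'   returns a [freq_trace()].
#' @export
write_trace_csv <- function(trace, path) {
  df <- tibble(time_s = trace$time_s, omega_hz = trace$omega_hz,
               valid = as.integer(trace$valid))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found (missing): %s", path))
  df <- utils::read.csv(path)
  if (!all(c("time_s", "omega_hz", "valid") %in% names(df))) {
    abort(sprintf("%s is not a trace CSV (time_s, omega_hz, valid).", path))
  }
  freq_trace(df$time_s, df$omega_hz, df$valid == 1)
}

#' Write detected events to CSV
#'
#' Columns: `pair_id`, `recording_id`, `ratio`, `start_s`, `end_s`,
#' `duration_s`.
#'
#' @param events Events tibble (with `recording_id`/`pair_id` columns
#'   where available).
#' @param path File path.
#' @export
write_events_csv <- function(events, path) {
  df <- as_tibble(events)
  if (!"recording_id" %in% names(df)) df$recording_id <- NA_character_
  if (!"pair_id" %in% names(df)) df$pair_id <- NA_character_
  df <- df |>
    transmute(pair_id = .data$pair_id, recording_id = .data$recording_id,
              ratio = .data$label, start_s = .data$start_s,
              end_s = .data$end_s, duration_s = .data$duration_s)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' YAML or JSON with (all optional) top-level keys `detection`
#' (`w`, `delta`, `tau`, `delta_tau`, `ratios` as a list of `[p, q]`
#' pairs, `gap_handling`), `filter` (`search_band_hz`,
#' `coarse_window_s`, `hop_s`, `relative_bandwidth`), `overlap`
#' (`window_s`, `bin_hz`, `harmonics` as `[k_a, k_b]`), `cv`
#' (`window_s`), `out_dir` and `seed`. Omitted keys fall back to the
#' package defaults. Command-line flags of the bundled front end
#' override these one-to-one.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(pipeline_config, raw)
}

#' Assemble a pipeline configuration
#'
#' @param detection,filter,overlap,cv Named lists of overrides for
#'   [detection_config()], [filter_spec()], [windowed_histograms()]
#'   (plus `harmonics`, the harmonic numbers of the two channels used
#'   for the overlap waterfall, default `c(2, 3)` for the shared
#'   male-second/female-third overtone) and [local_cv()].
#' @param out_dir Output directory for CSV/JSON products.
#' @param seed Integer seed for any stochastic step.
#' @param ... Additional keys kept verbatim.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(detection = list(), filter = list(),
                            overlap = list(), cv = list(),
                            out_dir = ".", seed = 1, ...) {
  if (!is.null(detection$ratios) && !is.data.frame(detection$ratios)) {
    m <- do.call(rbind, detection$ratios)
    detection$ratios <- tibble(p = as.integer(m[, 1]), q = as.integer(m[, 2]))
  }
  det <- do.call(detection_config, detection)
  flt <- do.call(filter_spec, filter)
  ov <- modifyList(list(window_s = 1, bin_hz = 1, harmonics = c(2, 3)),
                   overlap)
  cvw <- modifyList(list(window_s = 0.25), cv)
  structure(list(detection = det, filter = flt, overlap = ov, cv = cvw,
                 out_dir = out_dir, seed = seed, extra = list(...)),
            class = "pipeline_config")
}

process_recording <- function(rec, config) {
  # rec: one row of the recordings map (list), with either `wav` or
  # `trace_a`/`trace_b` paths
  if (!is.null(rec$wav) && !is.na(rec$wav)) {
    chans <- read_pair_wav(rec$wav, expect_channels = 2)
    tr_a <- track_fundamental(chans[[1]], config$filter)
    tr_b <- track_fundamental(chans[[2]], config$filter)
  } else {
    tr_a <- read_trace_csv(rec$trace_a)
    tr_b <- read_trace_csv(rec$trace_b)
  }
  rs <- ratio_series(tr_a, tr_b)
  ss <- separation_series(tr_a, tr_b)
  ev <- detect_events(rs, config$detection)
  ha <- windowed_histograms(tr_a, k = config$overlap$harmonics[1],
                            window_s = config$overlap$window_s,
                            bin_hz = config$overlap$bin_hz)
  hb <- windowed_histograms(tr_b, k = config$overlap$harmonics[2],
                            window_s = config$overlap$window_s,
                            bin_hz = config$overlap$bin_hz)
  ov <- overlap_series(ha, hb)
  cva <- local_cv(tr_a, config$cv$window_s)
  cvb <- local_cv(tr_b, config$cv$window_s)
  masked_frac <- 1 - mean(rs$valid)
  if (masked_frac > 0.2) {
    warn(sprintf("%s: %.0f%% of the ratio series is masked.",
                 rec$recording_id, 100 * masked_frac))
  }
  list(trace_a = tr_a, trace_b = tr_b, ratio = rs, separation = ss,
       events = ev, overlap = ov, cv_a = cva, cv_b = cvb)
}

#' Run the full analysis pipeline over a cohort of recordings
#'
#' For each recording (a two-channel WAV, or a pair of pre-extracted
#' trace CSVs): extracts both fundamental traces, builds the ratio and
#' separation series, detects convergence events, and computes the
#' histogram-overlap and local-c_v series. Writes per-recording CSVs and
#' cohort-level products (events table, cohort event summary and flight
#' statistics as JSON) under `config$out_dir`. Per-recording failures
#' are logged in the manifest and skipped; the run fails only if every
#' recording fails. Deterministic for a fixed config and seed.
#'
#' @param recordings A data frame with columns `recording_id`, `pair_id`
#'   and either `wav` (two-channel WAV path) or `trace_a` + `trace_b`
#'   (trace CSV paths).
#' @param config A [pipeline_config()].
#' @return A `run_manifest` tibble (`recording_id`, `status`, `message`),
#'   invisibly carrying the cohort products in attribute `products`.
#' @export
run_pipeline <- function(recordings, config = pipeline_config()) {
  recordings <- as_tibble(recordings)
  if (nrow(recordings) == 0) abort("No input recordings.")
  local_seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  statuses <- character(nrow(recordings))
  messages <- character(nrow(recordings))
  all_events <- list()
  all_traces <- list()
  for (i in seq_len(nrow(recordings))) {
    rec <- as.list(recordings[i, ])
    res <- tryCatch({
      msgs <- character()
      out <- withCallingHandlers(process_recording(rec, config),
        warning = function(w) {
          msgs <<- c(msgs, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      rid <- rec$recording_id
      write_trace_csv(out$trace_a, file.path(config$out_dir,
                                             paste0(rid, "_trace_a.csv")))
      write_trace_csv(out$trace_b, file.path(config$out_dir,
                                             paste0(rid, "_trace_b.csv")))
      utils::write.csv(as_tibble(out$ratio),
                       file.path(config$out_dir, paste0(rid, "_ratio.csv")),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(out$overlap,
                       file.path(config$out_dir, paste0(rid, "_overlap.csv")),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(as_tibble(out$cv_a),
                       file.path(config$out_dir, paste0(rid, "_cv_a.csv")),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(as_tibble(out$cv_b),
                       file.path(config$out_dir, paste0(rid, "_cv_b.csv")),
                       row.names = FALSE, quote = FALSE)
      ev <- as_tibble(out$events)
      if (nrow(ev)) {
        ev$recording_id <- rid
        ev$pair_id <- rec$pair_id
      }
      all_events[[rid]] <- ev
      all_traces[[paste0(rid, "_a")]] <- out$trace_a
      all_traces[[paste0(rid, "_b")]] <- out$trace_b
      list(status = "ok",
           message = paste(msgs, collapse = "; "))
    }, error = function(e) list(status = "failed",
                                message = conditionMessage(e)))
    statuses[i] <- res$status
    messages[i] <- res$message
  }
  if (all(statuses == "failed")) {
    abort(paste0("All recordings failed. First error: ", messages[1]))
  }
  events <- bind_rows(all_events)
  write_events_csv(events, file.path(config$out_dir, "events.csv"))
  summary <- summarize_cohort(
    events, recordings |> select("recording_id", "pair_id"))
  stats <- cohort_flight_stats(all_traces)
  jsonlite::write_json(as.list(summary),
                       file.path(config$out_dir, "event_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(as.list(as_tibble(stats)),
                       file.path(config$out_dir, "flight_stats.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- tibble(recording_id = recordings$recording_id,
                     status = statuses, message = messages)
  class(manifest) <- c("run_manifest", class(manifest))
  attr(manifest, "products") <- list(events = events, summary = summary,
                                     flight_stats = stats)
  invisible(manifest)
}
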
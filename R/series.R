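# Internal constructors and helpers shared by the time-series classes.
#
# All series are plain tibbles with a time_s column plus value/valid columns,
# carrying the sampling rate (and, for traces, subject metadata) as
# attributes so they survive piping through the package's own verbs.

new_series <- function(df, class, sample_rate_hz, subject = NULL, ...) {
  out <- as_tibble(df)
  attr(out, "sample_rate_hz") <- sample_rate_hz
  if (!is.null(subject)) attr(out, "subject") <- subject
  extra <- list(...)
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  class(out) <- c(class, class(tibble()))
  out
}

#' Construct a frequency trace
#'
#' A frequency trace is a tibble with columns `time_s`, `omega_hz`
#' (instantaneous fundamental wing-beat frequency) and `valid` (`FALSE`
#' inside flight-cessation gaps and filter edge zones), carrying the
#' sampling rate and optional subject metadata as attributes.
#'
#' @param time_s Numeric vector of sample times in seconds.
#' @param omega_hz Numeric vector of instantaneous frequencies in Hz;
#'   must be positive wherever `valid` is `TRUE`.
#' @param valid Logical vector, same length as `omega_hz`.
#' @param sample_rate_hz Sampling rate of the trace in samples per second.
#' @param subject Optional named list of subject metadata (e.g. `id`,
#'   `sex`, `treatment`).
#'
#' @return A tibble of class `freq_trace`.
#' @export
freq_trace <- function(time_s, omega_hz, valid = TRUE,
                       sample_rate_hz = NULL, subject = NULL) {
  n <- length(omega_hz)
  valid <- rep_len(as.logical(valid), n)
  if (length(time_s) != n) {
    abort("`time_s` and `omega_hz` must have equal length.")
  }
  if (any(valid & (!is.finite(omega_hz) | omega_hz <= 0))) {
    abort("`omega_hz` must be positive and finite at every valid sample.")
  }
  if (is.null(sample_rate_hz)) {
    sample_rate_hz <- if (n > 1) 1 / median(diff(time_s)) else NA_real_
  }
  new_series(tibble(time_s = as.numeric(time_s),
                    omega_hz = as.numeric(omega_hz), valid = valid),
             "freq_trace", sample_rate_hz, subject = subject)
}

#' Sampling rate of a series
#'
#' @param x A series object created by this package (trace, audio, ratio,
#'   ...). Falls back to the median time step when the attribute has been
#'   stripped by external manipulation.
#' @return Sampling rate in samples per second.
#' @export
sample_rate <- function(x) {
  sr <- attr(x, "sample_rate_hz")
  if (!is.null(sr)) return(sr)
  if (is.data.frame(x) && "time_s" %in% names(x) && nrow(x) > 1) {
    return(1 / median(diff(x$time_s)))
  }
  abort("Cannot determine the sampling rate of `x`.")
}

# time column used by series verbs (PAA accepts reduced series too)
time_col <- function(x) if (inherits(x, "paa_series")) "t_start" else "time_s"

# value column auto-detection for generic series verbs
value_col <- function(x, value = NULL) {
  if (!is.null(value)) return(value)
  cand <- intersect(c("ratio", "omega_hz", "delta_hz", "value", "amplitude"),
                    names(x))
  if (length(cand) == 0) {
    abort("No value column found; supply `value` explicitly.")
  }
  cand[[1]]
}

valid_of <- function(x) {
  if ("valid" %in% names(x)) x$valid else rep(TRUE, nrow(x))
}

# deterministic RNG scope: functions taking a `seed` leave the global
# RNG stream untouched
local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    abort("`seed` must be a single finite number.")
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  withr::defer({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, envir = envir)
  set.seed(as.integer(seed))
}

is_wholenumber <- function(x, tol = 1e-8) {
  is.numeric(x) & is.finite(x) & abs(x - round(x)) < tol
}

#' @export
print.freq_trace <- function(x, ...) {
  sr <- attr(x, "sample_rate_hz")
  subj <- attr(x, "subject")
  cat(sprintf("# A frequency trace: %d samples at %s Hz (%.3g s, %.1f%% valid)\n",
              nrow(x), format(sr), nrow(x) / sr,
              100 * mean(x$valid)))
  if (!is.null(subj) && length(subj)) {
    cat("# subject:", paste(names(subj), unlist(subj), sep = "=",
                            collapse = ", "), "\n")
  }
  NextMethod()
}
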
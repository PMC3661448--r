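# Core signal container and file I/O for EPG traces.

SCHEDULE_LABELS <- c("baseline", "5HT", "ethanol", "light_on", "light_off", "custom")

#' EPG trace container
#'
#' An `epg_trace` holds a uniformly sampled single-channel voltage recording
#' of pharyngeal pumping activity, in millivolts, together with its sampling
#' rate, start time, a free-text label (strain/condition) and an optional
#' condition schedule (drug wash-in, illumination epochs, ...).
#'
#' Units are fixed throughout the package: voltages in mV, times in seconds.
#' All event times reported downstream are absolute times in the trace's own
#' frame (starting at `t0`), never sample indices.
#'
#' @param samples Numeric vector of voltages (mV). Must be finite and of
#'   length >= 2.
#' @param rate Sampling rate in Hz (> 0).
#' @param t0 Time of the first sample in seconds (default 0).
#' @param label Free-text label carried through to reports.
#' @param schedule Optional condition schedule, see [epg_schedule()].
#' @return An object of class `epg_trace`.
#' @seealso [read_trace()], [write_trace()], [generate_trace()]
#' @export
epg_trace <- function(samples, rate, t0 = 0, label = "", schedule = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stopf("a trace needs at least 2 samples, got %d", length(samples))
  if (!all(is.finite(samples))) stopf("non-finite sample at index %d", which(!is.finite(samples))[1L])
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stopf("sampling rate must be a single positive number")
  if (!is.null(schedule)) schedule <- validate_schedule(schedule, t0, length(samples) / rate)
  structure(
    list(samples = samples, rate = as.numeric(rate), t0 = as.numeric(t0),
         label = as.character(label)[1L], schedule = schedule),
    class = "epg_trace")
}

#' Condition schedule
#'
#' A set of non-overlapping, sorted time intervals labelling experimental
#' conditions along a recording (e.g. baseline, drug wash-in, illumination).
#'
#' @param start_s,end_s Numeric vectors of interval starts and ends (seconds).
#' @param condition Character vector of labels, one of
#'   `r paste(SCHEDULE_LABELS, collapse = ", ")`.
#' @return A data frame of class `epg_schedule`.
#' @export
epg_schedule <- function(start_s, end_s, condition) {
  sched <- data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s),
                      condition = as.character(condition),
                      stringsAsFactors = FALSE)
  class(sched) <- c("epg_schedule", "data.frame")
  sched
}

validate_schedule <- function(sched, t0, duration) {
  if (!is.data.frame(sched) || !all(c("start_s", "end_s", "condition") %in% names(sched)))
    stopf("schedule must have columns start_s, end_s, condition")
  if (nrow(sched) == 0L) return(NULL)
  bad <- !sched$condition %in% SCHEDULE_LABELS
  if (any(bad)) stopf("unknown condition label '%s'", sched$condition[bad][1L])
  if (any(sched$end_s <= sched$start_s)) stopf("schedule intervals must have end > start")
  o <- order(sched$start_s)
  sched <- sched[o, , drop = FALSE]
  if (nrow(sched) > 1L && any(sched$start_s[-1L] < sched$end_s[-nrow(sched)] - 1e-9))
    stopf("schedule intervals overlap")
  if (sched$start_s[1L] < t0 - 1e-9 || sched$end_s[nrow(sched)] > t0 + duration + 1e-9)
    stopf("schedule intervals must lie within the recording [%g, %g]", t0, t0 + duration)
  rownames(sched) <- NULL
  class(sched) <- c("epg_schedule", "data.frame")
  sched
}

#' @export
print.epg_trace <- function(x, ...) {
  cat(sprintf("<epg_trace> %s\n", if (nzchar(x$label)) x$label else "(unlabelled)"))
  cat(sprintf("  %d samples @ %g Hz, %.3f s, t0 = %g s\n",
              length(x$samples), x$rate, trace_duration(x), x$t0))
  cat(sprintf("  range [%.3f, %.3f] mV\n", min(x$samples), max(x$samples)))
  if (!is.null(x$schedule))
    cat(sprintf("  schedule: %s\n",
                paste(sprintf("%s[%g-%gs]", x$schedule$condition, x$schedule$start_s,
                              x$schedule$end_s), collapse = " ")))
  invisible(x)
}

#' Trace duration and time axis
#'
#' `trace_duration()` is the canonical duration used by every consumer in the
#' package: number of samples divided by the sampling rate. `trace_times()`
#' returns the absolute time of each sample.
#'
#' @param trace An [epg_trace()].
#' @return Duration in seconds, or a numeric vector of times.
#' @export
trace_duration <- function(trace) length(trace$samples) / trace$rate

#' @rdname trace_duration
#' @export
trace_times <- function(trace) trace$t0 + (seq_along(trace$samples) - 1) / trace$rate

#' Read an EPG trace from a two-column CSV file
#'
#' The on-disk dialect is plain comma-separated text with a `time_s,signal_mV`
#' header, '.' decimal separator and optional `#`-prefixed metadata comment
#' lines (`# label: ...`, `# sampling_rate_hz: ...`, `# schedule: <JSON>`).
#' Time stamps must be strictly increasing and uniform to within a relative
#' tolerance of 1e-6 of the median step; the sampling rate is inferred from
#' the median time step.
#'
#' @param path Path to the file.
#' @param dialect File dialect; only `"csv_2col"` is supported. Proprietary
#'   acquisition formats (e.g. Axon ABF/ATF) are a plugin point, not
#'   implemented here.
#' @return An [epg_trace()].
#' @export
read_trace <- function(path, dialect = "csv_2col") {
  dialect <- match.arg(dialect, "csv_2col")
  if (!file.exists(path)) stopf("trace file does not exist: %s", path)
  lines <- readLines(path, warn = FALSE)
  is_comment <- startsWith(lines, "#")
  meta <- parse_trace_meta(lines[is_comment])
  body <- lines[!is_comment & nzchar(lines)]
  if (length(body) < 3L) stopf("trace file %s has fewer than 2 data rows", path)
  header <- strsplit(body[1L], ",", fixed = TRUE)[[1L]]
  if (length(header) < 2L) stopf("expected two columns 'time_s,signal_mV' in %s", path)
  con <- textConnection(body[-1L])
  on.exit(close(con))
  dat <- utils::read.csv(con, header = FALSE, colClasses = "character")
  tt <- suppressWarnings(as.numeric(dat[[1L]]))
  vv <- suppressWarnings(as.numeric(dat[[2L]]))
  bad <- which(!is.finite(tt) | !is.finite(vv))
  if (length(bad)) stopf("non-numeric cell in %s at data row %d", path, bad[1L])
  dt <- diff(tt)
  if (any(dt <= 0)) stopf("time stamps not strictly increasing in %s at index %d",
                          path, which(dt <= 0)[1L] + 1L)
  step <- stats::median(dt)
  off <- which(abs(dt - step) > 1e-6 * step)
  if (length(off)) stopf("non-uniform sampling in %s: time step at index %d deviates by %.3g (rel)",
                         path, off[1L] + 1L, abs(dt[off[1L]] - step) / step)
  # a rate recorded in the metadata header is authoritative (it restores the
  # exact rate on round trips); it must agree with the observed grid
  rate <- 1 / step
  if (!is.null(meta$rate)) {
    if (abs(meta$rate - rate) > 1e-6 * rate)
      stopf("header sampling_rate_hz (%g) disagrees with the time grid (%g) in %s",
            meta$rate, rate, path)
    rate <- meta$rate
  }
  epg_trace(vv, rate = rate, t0 = tt[1L],
            label = meta$label %||% "", schedule = meta$schedule)
}

parse_trace_meta <- function(comment_lines) {
  meta <- list(label = NULL, schedule = NULL, rate = NULL)
  for (ln in comment_lines) {
    ln <- sub("^#\\s*", "", ln)
    if (startsWith(ln, "label:")) meta$label <- trimws(sub("^label:", "", ln))
    if (startsWith(ln, "sampling_rate_hz:"))
      meta$rate <- as.numeric(trimws(sub("^sampling_rate_hz:", "", ln)))
    if (startsWith(ln, "schedule:")) {
      js <- trimws(sub("^schedule:", "", ln))
      sc <- jsonlite::fromJSON(js)
      if (NROW(sc)) meta$schedule <- epg_schedule(sc$start_s, sc$end_s, sc$condition)
    }
  }
  meta
}

#' Write an EPG trace to a two-column CSV file
#'
#' Writes the dialect read back by [read_trace()]. Samples are serialized at
#' full double precision so that a write/read round trip reproduces them
#' bit-identically. A schedule, when present, is serialized as JSON on a
#' single comment line; an empty schedule produces no schedule line.
#'
#' @param trace An [epg_trace()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "epg_trace"))
  con <- tryCatch(file(path, open = "wt"), error = function(e)
    stopf("cannot open %s for writing: %s", path, conditionMessage(e)))
  on.exit(close(con))
  writeLines(sprintf("# label: %s", trace$label), con)
  writeLines(sprintf("# sampling_rate_hz: %s", format(trace$rate, digits = 17)), con)
  if (!is.null(trace$schedule) && nrow(trace$schedule))
    writeLines(paste0("# schedule: ",
                      jsonlite::toJSON(as.data.frame(unclass(trace$schedule)), digits = NA)), con)
  writeLines("time_s,signal_mV", con)
  tt <- trace_times(trace)
  writeLines(sprintf("%.17g,%.17g", tt, trace$samples), con)
  invisible(path)
}
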
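# Per-recording EPG summary parameters and condition time-courses.

#' Compute the per-recording EPG parameters
#'
#' The seven standard summary metrics of an EPG recording, all derived from
#' the event table:
#' * `amp_pp`: mean over pumps of the peak-to-peak span `a_E - a_R` (mV);
#' * `frequency`: pump count divided by analyzed duration (pumps/s);
#' * `duration`: mean peak-E-to-peak-R interval (s);
#' * `re_interval`: mean interval from a pump's R peak to the next pump's E
#'   peak (s); gaps spanning a condition-schedule boundary are excluded so
#'   wash-in transients do not bias the statistic;
#' * `p_per_pump`: total P-wave count divided by pump count;
#' * `e_amp`: mean e amplitude over pumps with a detected e (baseline-
#'   relative peak height, mV); `NA` when no e was detected anywhere;
#' * `re_ratio`: mean per-pump `|a_R| / a_E`, a waveform-shape summary.
#'
#' @param events An `epg_events` table from [detect_pumps()].
#' @param trace Optional [epg_trace()]; supplies the analyzed duration and
#'   schedule when the event table lacks them.
#' @return A one-row data frame of class `epg_params` with the seven metrics
#'   plus `n_pumps` and `analyzed_s`. An empty event table gives an
#'   all-missing record with `n_pumps = 0`.
#' @export
compute_parameters <- function(events, trace = NULL) {
  ev <- as.data.frame(events)
  analyzed <- attr(events, "analyzed_s") %||% NA_real_
  if (!is.null(trace)) analyzed <- trace_duration(trace)
  if (is.na(analyzed)) stopf("analyzed duration unknown: supply the trace")
  worm_id <- attr(events, "worm_id") %||% ""
  if (nrow(ev) == 0L) {
    out <- data.frame(worm_id = worm_id, amp_pp = NA_real_, frequency = 0,
                      duration = NA_real_, re_interval = NA_real_,
                      p_per_pump = NA_real_, e_amp = NA_real_,
                      re_ratio = NA_real_, n_pumps = 0L, analyzed_s = analyzed,
                      stringsAsFactors = FALSE)
    class(out) <- c("epg_params", "data.frame")
    return(out)
  }
  ev <- ev[order(ev$t_E), , drop = FALSE]
  n <- nrow(ev)
  re_iv <- NA_real_
  if (n >= 2L) {
    gaps_start <- ev$t_R[-n]
    gaps_end <- ev$t_E[-1L]
    keep <- rep(TRUE, n - 1L)
    sched <- if (!is.null(trace)) trace$schedule else NULL
    if (!is.null(sched) && nrow(sched)) {
      bounds <- sort(unique(c(sched$start_s, sched$end_s)))
      for (b in bounds) keep <- keep & !(gaps_start < b & gaps_end > b)
    }
    if (any(keep)) re_iv <- mean(gaps_end[keep] - gaps_start[keep])
  }
  e_vals <- ev$a_e[!is.na(ev$a_e)]
  out <- data.frame(
    worm_id = worm_id,
    amp_pp = mean(ev$a_E - ev$a_R),
    frequency = n / analyzed,
    duration = mean(ev$t_R - ev$t_E),
    re_interval = re_iv,
    p_per_pump = sum(ev$n_P) / n,
    e_amp = if (length(e_vals)) mean(e_vals) else NA_real_,
    re_ratio = mean(abs(ev$a_R) / ev$a_E),
    n_pumps = n, analyzed_s = analyzed,
    stringsAsFactors = FALSE)
  class(out) <- c("epg_params", "data.frame")
  out
}

#' @export
print.epg_params <- function(x, ...) {
  cat(sprintf("<epg_params> %s: %d pumps / %.1f s\n",
              if (nzchar(x$worm_id)) x$worm_id else "(recording)",
              x$n_pumps, x$analyzed_s))
  cat(sprintf("  frequency %.3f /s | duration %.4f s | P/pump %.3f\n",
              x$frequency, x$duration, x$p_per_pump))
  cat(sprintf("  amp_pp %.3f mV | e %.3f mV | R/E %.3f | R-E interval %.3f s\n",
              x$amp_pp, x$e_amp, x$re_ratio, x$re_interval))
  invisible(x)
}

#' Binned time course of pump frequency and duration
#'
#' Pumps are binned by their E-peak time over contiguous, non-overlapping
#' bins covering the analyzed interval. Per-bin frequency is count divided
#' by bin width; per-bin duration is the mean E-to-R interval of the pumps
#' in the bin (`NA` for empty bins).
#'
#' @param events An `epg_events` table.
#' @param bin_width Bin width in seconds.
#' @param t_range Optional two-vector overriding the analyzed interval.
#' @return A data frame of class `epg_timecourse` with columns `bin_start_s`,
#'   `frequency`, `duration`, `n` and attribute `bin_width`.
#' @export
frequency_timecourse <- function(events, bin_width, t_range = NULL) {
  if (bin_width <= 0) stopf("bin_width must be positive")
  ev <- as.data.frame(events)
  if (is.null(t_range)) {
    t0 <- attr(events, "t0") %||% 0
    t_range <- c(t0, t0 + (attr(events, "analyzed_s") %||%
                             (if (nrow(ev)) max(ev$t_R) else bin_width)))
  }
  n_bins <- max(1L, ceiling((t_range[2L] - t_range[1L]) / bin_width - 1e-9))
  starts <- t_range[1L] + (seq_len(n_bins) - 1L) * bin_width
  idx <- if (nrow(ev)) findInterval(ev$t_E, c(starts, t_range[2L] + 1e-9),
                                    rightmost.closed = FALSE) else integer(0)
  n_in <- tabulate(idx[idx >= 1L & idx <= length(starts)], nbins = length(starts))
  durs <- rep(NA_real_, length(starts))
  for (b in seq_along(starts)) {
    sel <- idx == b
    if (any(sel)) durs[b] <- mean(ev$t_R[sel] - ev$t_E[sel])
  }
  out <- data.frame(bin_start_s = starts, frequency = n_in / bin_width,
                    duration = durs, n = n_in)
  structure(out, class = c("epg_timecourse", "data.frame"), bin_width = bin_width)
}

#' Per-condition summary of a time course
#'
#' Averages the binned frequency and duration within each labelled schedule
#' interval, using the bins fully contained in the interval. Intervals
#' covering no complete bin yield missing values with a warning.
#'
#' @param tc An `epg_timecourse` from [frequency_timecourse()].
#' @param schedule An [epg_schedule()].
#' @return A data frame with one row per schedule interval: condition,
#'   start/end, number of bins, mean frequency and mean duration.
#' @export
epoch_summary <- function(tc, schedule) {
  stopifnot(inherits(tc, "epg_timecourse"))
  bw <- attr(tc, "bin_width")
  out <- lapply(seq_len(nrow(schedule)), function(i) {
    sel <- tc$bin_start_s >= schedule$start_s[i] - 1e-9 &
           tc$bin_start_s + bw <= schedule$end_s[i] + 1e-9
    if (!any(sel)) {
      warnf("schedule interval %s [%g, %g] covers no complete bin",
            schedule$condition[i], schedule$start_s[i], schedule$end_s[i])
      return(data.frame(condition = schedule$condition[i],
                        start_s = schedule$start_s[i], end_s = schedule$end_s[i],
                        n_bins = 0L, frequency = NA_real_, duration = NA_real_,
                        stringsAsFactors = FALSE))
    }
    data.frame(condition = schedule$condition[i],
               start_s = schedule$start_s[i], end_s = schedule$end_s[i],
               n_bins = sum(sel),
               frequency = mean(tc$frequency[sel]),
               duration = mean(tc$duration[sel], na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Compare a metric between two groups of worms
#'
#' Welch two-sample t-test on per-worm metric values (the worm, not the
#' pump, is the statistical unit). Worms with a missing metric are excluded
#' with a warning.
#'
#' @param a,b Lists (or row-bound data frames) of `epg_params` records.
#' @param metric Metric name, e.g. `"duration"` or `"p_per_pump"`.
#' @return A list with the group means and standard errors, `t`, `df` and
#'   `p_value`.
#' @export
compare_groups <- function(a, b, metric) {
  pull <- function(g) {
    df <- if (is.data.frame(g)) g else do.call(rbind, g)
    if (!metric %in% names(df)) stopf("unknown metric '%s'", metric)
    v <- df[[metric]]
    if (anyNA(v)) {
      warnf("excluding %d worm(s) with missing %s", sum(is.na(v)), metric)
      v <- v[!is.na(v)]
    }
    v
  }
  va <- pull(a); vb <- pull(b)
  if (length(va) < 2L || length(vb) < 2L)
    stopf("need at least 2 worms per group with a defined %s", metric)
  se <- function(v) stats::sd(v) / sqrt(length(v))
  if (stats::sd(va) == 0 && stats::sd(vb) == 0 && mean(va) == mean(vb)) {
    ht <- list(statistic = c(t = 0), parameter = c(df = length(va) + length(vb) - 2),
               p.value = 1)
  } else ht <- stats::t.test(va, vb)
  list(metric = metric,
       mean_a = mean(va), se_a = se(va), n_a = length(va),
       mean_b = mean(vb), se_b = se(vb), n_b = length(vb),
       t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Write per-worm parameter records as JSON
#'
#' One record per worm with the metric fields plus provenance.
#'
#' @param params_list List of `epg_params` records (or a row-bound data
#'   frame).
#' @param path Output path.
#' @param provenance Optional named list echoed into every record.
#' @return Invisibly, `path`.
#' @export
write_params <- function(params_list, path, provenance = NULL) {
  df <- if (is.data.frame(params_list)) params_list else do.call(rbind, params_list)
  recs <- lapply(seq_len(nrow(df)), function(i) {
    rec <- as.list(df[i, , drop = FALSE])
    rec <- lapply(rec, function(v) if (is.factor(v)) as.character(v) else v)
    if (!is.null(provenance)) rec$provenance <- provenance
    rec
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}
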
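# Segmentation of a trace into pumps and labelling of the five phases.
#
# All thresholds are multiples of a robust noise sigma (1.4826 x MAD), never
# absolute millivolts, so one configuration serves adult-scale and
# amplitude-scaled (e.g. larval) recordings alike. Candidate extrema are
# located on lightly smoothed copies of the signal (a short boxcar matched
# to roughly half a transient width); this keeps single noise samples from
# spawning candidates while attenuating a 10 ms transient by only ~2 %.

#' Detection configuration
#'
#' @param spike_threshold_k E/R candidate threshold in noise-sigma multiples
#'   (default 5).
#' @param min_inter_pump Minimum silent separation between consecutive pumps
#'   in seconds (default 0.05).
#' @param max_ER_interval Maximum E-to-R pairing interval in seconds
#'   (default 0.5, accommodating the longest published mean duration,
#'   0.287 s, with margin).
#' @param e_search_window Two numbers: seconds before the E peak in which to
#'   look for the e spike (default `c(0.005, 0.060)`).
#' @param r_search_window Seconds after the R peak in which to look for the
#'   r spike (default `c(0.005, 0.120)`).
#' @param p_threshold_k e/P/r labelling threshold in sigma multiples
#'   (default 4; must not exceed `spike_threshold_k`).
#' @param p_exclusion_radius Seconds around the R peak excluded from P-wave
#'   search (default 0.010).
#' @param p_post_e_exclusion Seconds after the E peak excluded from P-wave
#'   search (default 0, i.e. disabled; the lobe-compensated threshold below
#'   handles the high-pass undershoot after large E spikes).
#' @param p_lobe_zone,p_lobe_frac Within `p_lobe_zone` seconds after the E
#'   peak (default 0.040), a P candidate must exceed the sigma threshold
#'   plus `p_lobe_frac` (default 0.06) times the E height: the zero-phase
#'   high-pass leaves an undershoot lobe of about that relative depth right
#'   after a large spike, which would otherwise masquerade as P waves.
#' @param p_merge Minima closer than this many seconds are merged into one
#'   P wave (default 0.004, about half the default P width).
#' @param p_max_width Maximum half-depth width (seconds) of a P-wave dip
#'   (default 0.020, about 2.5 transient FWHMs); broader dips are filter
#'   undershoot or residual drift, not P waves.
#' @param p_rel_floor P-wave dips shallower (on the detection channel) than
#'   this fraction of the recording's 90th-percentile dip depth are
#'   discarded (default 0.25): genuine P depths cluster within a factor ~2,
#'   far above threshold-grazing noise dips at high SNR, while at low SNR
#'   the floor falls below the sigma threshold and has no effect. Set to 0
#'   to disable.
#' @param smooth_ms Boxcar width (milliseconds) of the spike channel used
#'   for E/R/e/r candidates (default 3).
#' @param p_smooth_ms Boxcar width for the P-wave channel, matched to the
#'   wider/smaller P transients (default 6).
#' @param plateau_margin Seconds inside the E-R interval excluded (on both
#'   sides) from the plateau used as the per-pump local amplitude baseline
#'   (default 0.018, clearing the E and R transient flanks).
#' @param baseline_window Running-median baseline window in seconds
#'   (default 2), see [estimate_baseline()].
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(spike_threshold_k = 5, min_inter_pump = 0.05,
                             max_ER_interval = 0.5,
                             e_search_window = c(0.005, 0.060),
                             r_search_window = c(0.005, 0.120),
                             p_threshold_k = 4, p_exclusion_radius = 0.010,
                             p_post_e_exclusion = 0,
                             p_lobe_zone = 0.040, p_lobe_frac = 0.06,
                             p_merge = 0.004, p_max_width = 0.020,
                             p_rel_floor = 0.25,
                             smooth_ms = 3, p_smooth_ms = 6,
                             plateau_margin = 0.018, baseline_window = 2) {
  if (p_threshold_k > spike_threshold_k)
    stopf("p_threshold_k must not exceed spike_threshold_k")
  if (any(c(e_search_window, r_search_window) <= 0) ||
      e_search_window[1L] >= e_search_window[2L] ||
      r_search_window[1L] >= r_search_window[2L])
    stopf("search windows must be positive increasing pairs")
  structure(list(spike_threshold_k = spike_threshold_k,
                 min_inter_pump = min_inter_pump,
                 max_ER_interval = max_ER_interval,
                 e_search_window = e_search_window,
                 r_search_window = r_search_window,
                 p_threshold_k = p_threshold_k,
                 p_exclusion_radius = p_exclusion_radius,
                 p_post_e_exclusion = p_post_e_exclusion,
                 p_lobe_zone = p_lobe_zone, p_lobe_frac = p_lobe_frac,
                 p_merge = p_merge, p_max_width = p_max_width,
                 p_rel_floor = p_rel_floor,
                 smooth_ms = smooth_ms,
                 p_smooth_ms = p_smooth_ms, plateau_margin = plateau_margin,
                 baseline_window = baseline_window),
            class = "detection_config")
}

# candidate pairing and greedy conflict resolution shared by the two
# detection passes: each E candidate is paired with the deepest trough
# within `maxER` samples (when `cut_windows`, also before the next E
# candidate more than `ip` samples away, which stops pairing from reaching
# into the following pump at high pump rates); pairs are then accepted
# greedily by descending combined spike magnitude, rejecting overlaps,
# shared troughs and pumps closer than `ip` samples
pair_pumps <- function(ys, maxs, mins, thrE, thrR, ip, maxER, cut_windows = TRUE) {
  Ecand <- maxs[ys[maxs] > thrE]
  Rcand <- mins[ys[mins] < -thrR]
  if (!length(Ecand) || !length(Rcand)) return(list(E = integer(0), R = integer(0)))
  pe <- integer(0); pr <- integer(0)
  for (i in Ecand) {
    hi <- min(i + maxER, length(ys))
    if (cut_windows) {
      nxt <- Ecand[Ecand > i + ip]
      if (length(nxt)) hi <- min(hi, nxt[1L] - 1L)
    }
    rc <- Rcand[Rcand > i & Rcand <= hi]
    if (!length(rc)) next
    pe <- c(pe, i); pr <- c(pr, rc[which.min(ys[rc])])
  }
  if (!length(pe)) return(list(E = integer(0), R = integer(0)))
  ord <- order(ys[pe] - ys[pr], decreasing = TRUE)
  acc_E <- integer(0); acc_R <- integer(0)
  for (k in ord) {
    e_i <- pe[k]; r_i <- pr[k]
    if (length(acc_E)) {
      conflict <- any(!(e_i > acc_R + ip | r_i < acc_E - ip)) || r_i %in% acc_R
      if (conflict) next
    }
    acc_E <- c(acc_E, e_i); acc_R <- c(acc_R, r_i)
  }
  o <- order(acc_E)
  list(E = acc_E[o], R = acc_R[o])
}

# peak value by least-squares parabola through the raw samples around a
# located extremum index: immune to the boxcar attenuation of the smoothed
# detection channels and averages a little noise; falls back to the sample
# value when the window is degenerate
quad_peak <- function(x, i, half = 3L) {
  lo <- max(1L, i - half); hi <- min(length(x), i + half)
  if (hi - lo < 2L) return(x[i])
  k <- (lo:hi) - i
  fit <- stats::lm.fit(cbind(1, k, k * k), x[lo:hi])
  b <- fit$coefficients
  if (!is.finite(b[3L]) || b[3L] == 0) return(x[i])
  v <- -b[2L] / (2 * b[3L])
  v <- min(max(v, k[1L]), k[length(k)])
  unname(b[1L] + b[2L] * v + b[3L] * v * v)
}

empty_events <- function(trace, sigma = NA_real_, worm_id = "") {
  ev <- data.frame(worm_id = character(0), pump_index = integer(0),
                   t_e = numeric(0), a_e = numeric(0),
                   t_E = numeric(0), a_E = numeric(0), n_P = integer(0),
                   t_R = numeric(0), a_R = numeric(0),
                   t_r = numeric(0), a_r = numeric(0),
                   flags = character(0), stringsAsFactors = FALSE)
  ev$t_P <- list()
  ev$a_P <- list()
  structure(ev, class = c("epg_events", "data.frame"),
            sigma = sigma, analyzed_s = trace_duration(trace),
            rate = trace$rate, t0 = trace$t0, worm_id = worm_id)
}

#' Detect pumps and label the e, E, P, R, r phases
#'
#' The detector (1) estimates a robust noise sigma as 1.4826 x MAD of the
#' baseline-subtracted signal, (2) collects candidate E peaks (local maxima
#' above `spike_threshold_k` sigma) and candidate R troughs (local minima
#' below the negated threshold), (3) pairs each E with the deepest following
#' trough within `max_ER_interval` (and before the next major E candidate),
#' (4) resolves conflicting pairs greedily by descending combined spike
#' magnitude while enforcing the minimum inter-pump separation, and (5)
#' labels the small phases per pump: e as the largest sub-threshold-exempt
#' local maximum shortly before E, r as the largest local minimum shortly
#' after R, and P waves as all local minima in the open E-R plateau beyond
#' `p_threshold_k` sigma, clear of R by `p_exclusion_radius`, merged when
#' closer than `p_merge`.
#'
#' The trace should be drift-filtered first (see [highpass()]); a running
#' median baseline is subtracted internally, which tolerates mild residual
#' drift.
#'
#' @param trace An [epg_trace()].
#' @param cfg A [detection_config()].
#' @param worm_id Identifier carried into the event table.
#' @return An `epg_events` data frame, one row per pump, sorted by `t_E`,
#'   with list columns `t_P`/`a_P`, signed amplitudes relative to the local
#'   baseline (mV), and attributes `sigma` (noise estimate), `analyzed_s`,
#'   `rate`, `t0`.
#' @export
detect_pumps <- function(trace, cfg = detection_config(), worm_id = "") {
  stopifnot(inherits(trace, "epg_trace"), inherits(cfg, "detection_config"))
  rate <- trace$rate
  x <- trace$samples
  if (trace_duration(trace) < 2 * cfg$min_inter_pump) {
    warnf("trace shorter than 2 x min_inter_pump; returning empty event table")
    return(empty_events(trace, worm_id = worm_id))
  }
  base <- running_median_fast(x, round(cfg$baseline_window * rate))
  ys <- moving_average(x, max(1L, round(cfg$smooth_ms / 1000 * rate))) - base
  yp <- moving_average(x, max(1L, round(cfg$p_smooth_ms / 1000 * rate))) - base
  # P channel is additionally detrended with a short running median: it
  # follows the broad, shallow undershoot a zero-phase high-pass leaves
  # around large spikes, but cannot follow a narrow P dip, so P-wave
  # thresholding sees the dip alone. The un-detrended copy locates the e
  # spike (same width class as P; the lower-noise channel halves the
  # pick-the-largest selection bias of the e amplitude).
  ype <- yp
  yp <- yp - running_median(yp, round(0.041 * rate))
  sig_s <- stats::mad(ys)

  maxs <- local_maxima(ys)
  mins <- local_minima(ys)
  thr <- cfg$spike_threshold_k * sig_s
  ip <- as.integer(round(cfg$min_inter_pump * rate))
  maxER <- as.integer(round(cfg$max_ER_interval * rate))

  # Two passes. The coarse pass at the sigma threshold alone estimates the
  # spike scale of the recording: accepted pairs within the dominant
  # amplitude cluster (peak-to-peak at least 0.35 x the largest) give
  # median E and R heights. The refinement pass then requires candidates to
  # reach half those heights as well, which is self-calibrating in sigma
  # units: borderline noise maxima no longer seed pumps or truncate pairing
  # windows, and P/r troughs (at most ~half an R) are never mistaken for R.
  acc <- pair_pumps(ys, maxs, mins, thr, thr, ip, maxER, cut_windows = FALSE)

  # refine the sigmas on samples away from the E/R spike neighbourhoods:
  # the spikes themselves inflate a whole-signal MAD by ~25 % at high pump
  # rates, which would push every nominal sigma multiple well above its
  # stated value (losing low-amplitude pumps near the SNR floor and
  # raising the effective e/P/r threshold)
  refine_sigmas <- function(accs) {
    spike_mask <- rep(FALSE, length(ys))
    m_pre <- as.integer(round(0.045 * rate)); m_post <- as.integer(round(0.040 * rate))
    for (k in seq_along(accs$E)) {
      spike_mask[max(1L, accs$E[k] - m_pre):min(length(ys), accs$E[k] + m_post / 2L)] <- TRUE
      spike_mask[max(1L, accs$R[k] - m_post / 2L):min(length(ys), accs$R[k] + m_post)] <- TRUE
    }
    if (sum(!spike_mask) > 1000L)
      list(s = stats::mad(ys[!spike_mask]), p = stats::mad(yp[!spike_mask]),
           pe = stats::mad(ype[!spike_mask]))
    else list(s = sig_s, p = stats::mad(yp), pe = stats::mad(ype))
  }
  sig_p <- stats::mad(yp)
  sig_pe <- stats::mad(ype)
  if (length(acc$E) >= 3L) {
    sg <- refine_sigmas(acc)
    amp <- ys[acc$E] - ys[acc$R]
    big <- amp >= 0.35 * max(amp)
    if (sum(big) >= 3L) {
      thrE <- max(cfg$spike_threshold_k * sg$s, 0.5 * stats::median(ys[acc$E[big]]))
      thrR <- max(cfg$spike_threshold_k * sg$s, 0.5 * stats::median(-ys[acc$R[big]]))
      acc <- pair_pumps(ys, maxs, mins, thrE, thrR, ip, maxER)
    }
  }
  acc_E <- acc$E; acc_R <- acc$R
  if (!length(acc_E)) return(empty_events(trace, sig_s, worm_id))
  sg <- refine_sigmas(acc)
  sig_s <- sg$s; sig_p <- sg$p; sig_pe <- sg$pe

  minsp <- local_minima(yp)
  maxpe <- local_maxima(ype)
  Pcand_all <- minsp[yp[minsp] < -cfg$p_threshold_k * sig_p]
  t_of <- function(i) trace$t0 + (i - 1L) / rate
  n_pumps <- length(acc_E)
  rows <- vector("list", n_pumps)
  # per-pump local baseline: median of the raw signal over the pump's own
  # E-R plateau (transient flanks and detected P waves masked out); this is
  # the most local reference available and tracks the baseline shift a
  # zero-phase high-pass leaves under each pump complex, which the long
  # global running median cannot follow
  pl_off <- as.integer(round(cfg$plateau_margin * rate))
  p_mask <- as.integer(round(0.007 * rate))
  fl_out <- as.integer(round((cfg$e_search_window[2L] + 0.005) * rate))
  fl_len <- as.integer(round(0.030 * rate))
  for (k in seq_len(n_pumps)) {
    iE <- acc_E[k]; iR <- acc_R[k]
    # e: largest local max in the search window before E, above threshold
    # (located on the e-width-matched channel)
    w0 <- iE - as.integer(round(cfg$e_search_window[2L] * rate))
    w1 <- iE - as.integer(round(cfg$e_search_window[1L] * rate))
    ec <- maxpe[maxpe >= max(1L, w0) & maxpe <= w1 & maxpe != iE]
    ec <- ec[ype[ec] > cfg$p_threshold_k * sig_pe]
    i_e <- if (length(ec)) ec[which.max(ype[ec])] else NA_integer_
    # r: largest local min in the search window after R, below threshold
    w0 <- iR + as.integer(round(cfg$r_search_window[1L] * rate))
    w1 <- iR + as.integer(round(cfg$r_search_window[2L] * rate))
    if (k < n_pumps) w1 <- min(w1, acc_E[k + 1L] - 1L)
    rc <- mins[mins >= w0 & mins <= min(w1, length(ys)) & mins != iR]
    rc <- rc[ys[rc] < -cfg$p_threshold_k * sig_s]
    i_r <- if (length(rc)) rc[which.min(ys[rc])] else NA_integer_
    # P: minima in the open (E, R) plateau, clear of R, merged if close.
    # A width gate rejects broad dips: a genuine P wave is a narrow
    # transient (~8 ms FWHM), whereas the shallow undershoot lobe a
    # zero-phase high-pass leaves after a large E spike spans tens of ms.
    excl <- as.integer(round(cfg$p_exclusion_radius * rate))
    exclE <- as.integer(round(cfg$p_post_e_exclusion * rate))
    pc <- Pcand_all[Pcand_all > iE + exclE & Pcand_all < iR - excl]
    if (length(pc)) {
      # lobe-compensated threshold just after E (see p_lobe_zone above)
      zone <- as.integer(round(cfg$p_lobe_zone * rate))
      in_zone <- pc - iE <= zone
      deep <- yp[pc] < -(cfg$p_threshold_k * sig_p + cfg$p_lobe_frac * ys[iE])
      pc <- pc[!in_zone | deep]
    }
    if (length(pc)) {
      wmax <- as.integer(round(cfg$p_max_width * rate))
      narrow <- vapply(pc, function(i) {
        half <- yp[i] / 2
        l <- i; r <- i
        while (l > 1L && yp[l] < half && i - l <= wmax) l <- l - 1L
        while (r < length(yp) && yp[r] < half && r - i <= wmax) r <- r + 1L
        (r - l) <= wmax
      }, logical(1))
      pc <- pc[narrow]
    }
    if (length(pc) > 1L) {
      merge_n <- as.integer(round(cfg$p_merge * rate))
      grp <- cumsum(c(1L, diff(pc) > merge_n))
      pc <- vapply(split(pc, grp), function(ii) ii[which.min(yp[ii])], integer(1))
    }
    # local baseline: plateau median with P neighbourhoods masked,
    # falling back to a pre-pump flank, then to the global running median
    pl <- (iE + pl_off):(iR - pl_off)
    if (length(pc)) {
      masked <- unlist(lapply(pc, function(i) (i - p_mask):(i + p_mask)))
      pl <- setdiff(pl, masked)
    }
    # pre-pump flank baseline (the quiet stretch just before the e search
    # window): the e spike is referenced to it, being nearer to it than to
    # the plateau under the lift a zero-phase high-pass leaves
    f_hi <- iE - fl_out
    f_lo <- max(1L, f_hi - fl_len,
                if (k > 1L) acc_R[k - 1L] + fl_out else 1L)
    b_pre <- if (f_hi - f_lo >= 10L) stats::median(x[f_lo:f_hi]) else base[iE]
    b_k <- if (length(pl) >= 20L) stats::median(x[pl]) else b_pre
    # amplitudes: parabolic peak of the raw signal at the located index,
    # relative to the pump's local baseline
    a_P <- vapply(pc, function(i) quad_peak(x, i) - b_k, numeric(1))
    keepP <- a_P < 0
    pc <- pc[keepP]; a_P <- a_P[keepP]
    a_E <- quad_peak(x, iE) - b_k
    a_R <- quad_peak(x, iR) - b_k
    if (!(a_E > 0 && a_R < 0)) next  # degenerate local baseline; drop pump
    flags <- c(if (is.na(i_e)) "missing_e", if (is.na(i_r)) "missing_r")
    row <- data.frame(worm_id = worm_id, pump_index = k,
                      t_e = if (is.na(i_e)) NA_real_ else t_of(i_e),
                      a_e = if (is.na(i_e)) NA_real_ else quad_peak(x, i_e) - b_pre,
                      t_E = t_of(iE), a_E = a_E, n_P = length(pc),
                      t_R = t_of(iR), a_R = a_R,
                      t_r = if (is.na(i_r)) NA_real_ else t_of(i_r),
                      a_r = if (is.na(i_r)) NA_real_ else quad_peak(x, i_r) - b_k,
                      flags = if (length(flags)) paste(flags, collapse = ",")
                              else "complete",
                      stringsAsFactors = FALSE)
    row$b_pre <- b_pre
    row$b_plat <- b_k
    row$t_P <- list(t_of(pc))
    row$a_P <- list(unname(a_P))
    row$d_P <- list(unname(yp[pc]))   # detection-channel depths, for the floor
    rows[[k]] <- row
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty_events(trace, sig_s, worm_id))
  for (k in seq_along(rows)) rows[[k]]$pump_index <- k
  ev <- do.call(rbind, rows)
  # e amplitudes re-measured at the recording's median e-to-E lag: the e
  # spike is stereotyped relative to E, and reading every pump at the same
  # relative position removes the pick-the-largest selection bias that a
  # per-pump noisy localisation carries (~+5 % at basal e/noise ratios).
  # The e baseline interpolates linearly between the pre-pump flank and the
  # plateau medians: even after compensation the filter leaves a smooth
  # residual baseline profile under the complex, and the e spike sits
  # between the two measured baseline segments.
  has_e <- !is.na(ev$t_e)
  if (sum(has_e) >= 5L) {
    lag <- as.integer(stats::median(round((ev$t_E[has_e] - ev$t_e[has_e]) * rate)))
    iEs <- as.integer(round((ev$t_E - trace$t0) * rate)) + 1L
    iRs <- as.integer(round((ev$t_R - trace$t0) * rate)) + 1L
    ev$a_e[has_e] <- vapply(which(has_e), function(k) {
      i <- iEs[k] - lag
      w <- max(1L, i - 2L):min(length(x), i + 2L)
      i_flank <- iEs[k] - fl_out - fl_len %/% 2L
      i_plat <- (iEs[k] + iRs[k]) %/% 2L
      frac <- (i - i_flank) / max(i_plat - i_flank, 1L)
      frac <- min(max(frac, 0), 1)
      b_e <- ev$b_pre[k] + frac * (ev$b_plat[k] - ev$b_pre[k])
      mean(x[w]) - b_e             # plain local average: no vertex/max bias
    }, numeric(1))
  }
  ev$b_pre <- NULL
  ev$b_plat <- NULL
  # relative P floor on detection-channel depths: genuine P depths cluster
  # within a factor ~2 of the recording's deepest, while dips that merely
  # graze the sigma threshold are noise
  allD <- abs(unlist(ev$d_P))
  if (cfg$p_rel_floor > 0 && length(allD) >= 3L) {
    floorD <- cfg$p_rel_floor * stats::quantile(allD, 0.9, names = FALSE)
    for (k in seq_len(nrow(ev))) {
      keep <- abs(ev$d_P[[k]]) >= floorD
      if (!all(keep)) {
        ev$t_P[[k]] <- ev$t_P[[k]][keep]
        ev$a_P[[k]] <- ev$a_P[[k]][keep]
        ev$n_P[k] <- sum(keep)
      }
    }
  }
  ev$d_P <- NULL
  ev <- structure(ev, class = c("epg_events", "data.frame"),
                  sigma = sig_s, analyzed_s = trace_duration(trace),
                  rate = rate, t0 = trace$t0, worm_id = worm_id)
  validate_events(ev)
  ev
}

validate_events <- function(ev) {
  if (nrow(ev) == 0L) return(invisible(TRUE))
  stopifnot(all(ev$t_E < ev$t_R), all(ev$a_E > 0), all(ev$a_R < 0))
  for (k in seq_len(nrow(ev))) {
    tp <- ev$t_P[[k]]
    if (length(tp) && !(all(tp > ev$t_E[k]) && all(tp < ev$t_R[k])))
      stopf("internal: P wave outside its pump plateau")          # nocov
    if (length(ev$a_P[[k]]) && any(ev$a_P[[k]] >= 0))
      stopf("internal: non-negative P amplitude")                 # nocov
  }
  if (nrow(ev) > 1L && any(diff(ev$t_E) <= 0))
    stopf("internal: pumps not sorted by t_E")                    # nocov
  invisible(TRUE)
}

#' @export
print.epg_events <- function(x, ...) {
  cat(sprintf("<epg_events> %d pumps over %.1f s (sigma %.4g mV)\n",
              nrow(x), attr(x, "analyzed_s"), attr(x, "sigma")))
  if (nrow(x)) {
    df <- as.data.frame(x)[, c("pump_index", "t_E", "a_E", "n_P", "t_R", "a_R", "flags")]
    print(utils::head(df, 10))
    if (nrow(x) > 10) cat(sprintf("  ... %d more pumps\n", nrow(x) - 10L))
  }
  invisible(x)
}

#' Head-first orientation quality gate
#'
#' Recordings from worms trapped tail first have small, featureless signals:
#' they lack the e/P/r detail of a true head EPG. The gate returns
#' `tail_or_bad` when the median per-pump peak-to-peak amplitude is below a
#' quarter of `reference_amp`, or when (with at least 10 pumps) fewer than
#' 5 % of pumps carry any detected e, P or r feature. Traces with fewer than
#' `min_pumps` detected pumps are rejected with reason `too_few_events`.
#'
#' @param trace An [epg_trace()] (drift-filtered).
#' @param cfg A [detection_config()].
#' @param reference_amp Reference head-recording peak-to-peak amplitude in
#'   mV (default 4.410, the wild-type on-chip value).
#' @param events Optional pre-computed event table for the trace.
#' @param min_pumps Minimum pump count to attempt the gate (default 3).
#' @return A list with `verdict` (`"head"` or `"tail_or_bad"`) and `reason`.
#' @export
orientation_gate <- function(trace, cfg = detection_config(),
                             reference_amp = 4.410, events = NULL,
                             min_pumps = 3L) {
  if (is.null(events))
    events <- suppressWarnings(detect_pumps(trace, cfg))
  ev <- as.data.frame(events)
  if (nrow(ev) < min_pumps)
    return(list(verdict = "tail_or_bad", reason = "too_few_events"))
  amp <- ev$a_E - ev$a_R
  if (stats::median(amp) < 0.25 * reference_amp)
    return(list(verdict = "tail_or_bad", reason = "low_amplitude"))
  if (nrow(ev) >= 10L) {
    has_feature <- !is.na(ev$t_e) | ev$n_P >= 1L | !is.na(ev$t_r)
    if (mean(has_feature) < 0.05)
      return(list(verdict = "tail_or_bad", reason = "no_epg_detail"))
  }
  list(verdict = "head", reason = "ok")
}

#' Write / read an event table as TSV
#'
#' One row per pump; the P-wave time and amplitude lists are
#' semicolon-joined. Attributes (noise sigma, analyzed duration, rate, t0)
#' travel in `#`-prefixed header comments.
#'
#' @param events An `epg_events` table.
#' @param path File path.
#' @return `read_events()` returns an `epg_events` table; `write_events()`
#'   its path, invisibly.
#' @export
write_events <- function(events, path) {
  ev <- as.data.frame(events)
  join <- function(col) vapply(col, function(v)
    paste(format(v, digits = 10, trim = TRUE, scientific = FALSE), collapse = ";"),
    character(1))
  flat <- data.frame(worm_id = ev$worm_id, pump_index = ev$pump_index,
                     t_e = ev$t_e, a_e = ev$a_e, t_E = ev$t_E, a_E = ev$a_E,
                     n_P = ev$n_P,
                     t_P_list = if (nrow(ev)) join(ev$t_P) else character(0),
                     a_P_list = if (nrow(ev)) join(ev$a_P) else character(0),
                     t_R = ev$t_R, a_R = ev$a_R, t_r = ev$t_r, a_r = ev$a_r,
                     flags = ev$flags, stringsAsFactors = FALSE)
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("# sigma_mV: %.10g", attr(events, "sigma")), con)
  writeLines(sprintf("# analyzed_s: %.10g", attr(events, "analyzed_s")), con)
  writeLines(sprintf("# rate_hz: %.10g", attr(events, "rate")), con)
  writeLines(sprintf("# t0_s: %.10g", attr(events, "t0")), con)
  utils::write.table(flat, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  get_num <- function(key) {
    ln <- hdr[grepl(paste0("^# ", key, ":"), hdr)]
    if (length(ln)) as.numeric(sub(paste0("^# ", key, ":\\s*"), "", ln[1L])) else NA_real_
  }
  con <- textConnection(lines[!startsWith(lines, "#")])
  on.exit(close(con))
  flat <- utils::read.table(con, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  split_num <- function(s) lapply(strsplit(ifelse(is.na(s) | s == "", "", s), ";"),
                                  function(v) as.numeric(v[nzchar(v)]))
  ev <- flat[, c("worm_id", "pump_index", "t_e", "a_e", "t_E", "a_E", "n_P",
                 "t_R", "a_R", "t_r", "a_r", "flags")]
  ev$t_P <- split_num(flat$t_P_list)
  ev$a_P <- split_num(flat$a_P_list)
  structure(ev, class = c("epg_events", "data.frame"),
            sigma = get_num("sigma_mV"), analyzed_s = get_num("analyzed_s"),
            rate = get_num("rate_hz"), t0 = get_num("t0_s"),
            worm_id = if (nrow(ev)) ev$worm_id[1L] else "")
}
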
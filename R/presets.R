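# Phenotype presets, pump kernel morphology and condition schedule effects
# for the EPG simulator.

#' Phenotype preset for the EPG simulator
#'
#' A preset is the generative parameter set for one strain/condition: mean
#' pump frequency and its between-pump coefficient of variation, mean pump
#' duration (peak-E-to-peak-R), mean P-wave count per pump (a Poisson
#' intensity), peak-to-peak amplitude (E-to-R span), e-spike amplitude, the
#' R/E amplitude ratio, and a single between-worm multiplicative spread
#' (`worm_cv`) applied to all means.
#'
#' Shipped presets (`epg_presets()`) reproduce the published on-chip and
#' conventional-microelectrode phenotypes for wild-type worms with and
#' without serotonin, for the eat-4 glutamatergic-signalling mutant, and a
#' `tail` preset emulating a worm trapped in the wrong orientation.
#'
#' @param name Preset name; either a shipped preset name or a path to a JSON
#'   preset file with the same fields.
#' @return An object of class `epg_preset` (a named list of parameters).
#' @examples
#' epg_preset("wt_basal_chip")$dur_mean   # 0.116 s
#' @export
epg_preset <- function(name) {
  path <- if (file.exists(name) && grepl("\\.json$", name)) name
          else system.file("extdata", "presets", paste0(name, ".json"), package = "epgtools")
  if (!nzchar(path) || !file.exists(path))
    stopf("unknown preset '%s'; shipped presets: %s", name,
          paste(epg_presets(), collapse = ", "))
  p <- jsonlite::fromJSON(path)
  validate_preset(p)
}

#' @rdname epg_preset
#' @export
epg_presets <- function() {
  dir <- system.file("extdata", "presets", package = "epgtools")
  sort(sub("\\.json$", "", list.files(dir, pattern = "\\.json$")))
}

validate_preset <- function(p) {
  num <- c("freq_mean", "freq_cv", "dur_mean", "dur_cv", "p_rate",
           "amp_pp_mean", "amp_pp_cv", "e_amp_mean", "re_ratio_mean", "worm_cv")
  missing <- setdiff(num, names(p))
  if (length(missing)) stopf("preset is missing fields: %s", paste(missing, collapse = ", "))
  for (f in num) p[[f]] <- as.numeric(p[[f]])
  with(p, {
    if (freq_mean < 0 || dur_mean <= 0 || amp_pp_mean <= 0 || re_ratio_mean <= 0)
      stopf("preset means must be positive")
    if (p_rate < 0 || e_amp_mean < 0) stopf("p_rate and e_amp_mean must be >= 0")
    cvs <- c(freq_cv, dur_cv, amp_pp_cv, worm_cv)
    if (any(cvs < 0) || any(cvs >= 1)) stopf("all cv values must lie in [0, 1)")
  })
  structure(p, class = "epg_preset")
}

#' @export
print.epg_preset <- function(x, ...) {
  cat(sprintf("<epg_preset> %s\n", x$name))
  cat(sprintf("  freq %g /s (cv %g)   duration %g s (cv %g)\n",
              x$freq_mean, x$freq_cv, x$dur_mean, x$dur_cv))
  cat(sprintf("  P/pump %g   amp_pp %g mV (cv %g)   e %g mV   R/E %g   worm_cv %g\n",
              x$p_rate, x$amp_pp_mean, x$amp_pp_cv, x$e_amp_mean,
              x$re_ratio_mean, x$worm_cv))
  invisible(x)
}

#' Pump kernel morphology
#'
#' Micro-timing and shape of the five transients making up one pump complex.
#' `e` leads the E peak by `e_lead`; `r` lags the R peak by `r_lag`; widths
#' are full widths at half maximum of the transient bumps. Defaults are
#' chosen so that all five phases are resolvable at a 2 kHz sampling rate.
#' The P transient amplitude is `p_rel_amp` times the E amplitude, an
#' intermediate size between the small e spike and the large R spike,
#' matching the published waveform morphology.
#'
#' @param e_lead Seconds the e peak precedes the E peak (default 0.025).
#' @param e_width,E_width,P_width,r_width Transient FWHM in seconds
#'   (defaults 0.008, 0.010, 0.008, 0.010).
#' @param r_lag Seconds the r peak follows the R peak (default 0.020).
#' @param r_rel_amp r amplitude as a fraction of the R amplitude (default 0.4).
#' @param p_rel_amp P amplitude as a fraction of the E amplitude (default 0.5).
#' @param shape Transient shape, `"gaussian"` (default) or `"biexponential"`.
#' @return An object of class `pump_kernel`.
#' @export
epg_kernel <- function(e_lead = 0.025, e_width = 0.008, E_width = 0.010,
                       P_width = 0.008, r_lag = 0.020, r_width = 0.010,
                       r_rel_amp = 0.4, p_rel_amp = 0.5,
                       shape = c("gaussian", "biexponential")) {
  shape <- match.arg(shape)
  widths <- c(e_width = e_width, E_width = E_width, P_width = P_width, r_width = r_width)
  if (any(widths <= 0)) stopf("all kernel widths must be positive")
  if (e_lead <= e_width / 2) stopf("e_lead must exceed e_width/2 so e is resolvable before E")
  if (r_rel_amp <= 0 || r_rel_amp >= 1) stopf("r_rel_amp must be in (0, 1)")
  if (p_rel_amp <= 0 || p_rel_amp >= 1) stopf("p_rel_amp must be in (0, 1)")
  structure(list(e_lead = e_lead, e_width = e_width, E_width = E_width,
                 P_width = P_width, r_lag = r_lag, r_width = r_width,
                 r_rel_amp = r_rel_amp, p_rel_amp = p_rel_amp, shape = shape),
            class = "pump_kernel")
}

check_kernel_vs_duration <- function(kernel, dur_mean) {
  widths <- c(kernel$e_width, kernel$E_width, kernel$P_width, kernel$r_width)
  if (any(widths >= dur_mean / 2))
    stopf("kernel widths (max %g s) are incompatible with pump duration %g s: every width must be < dur_mean/2",
          max(widths), dur_mean)
  invisible(TRUE)
}

#' Time-varying condition effect for the simulator
#'
#' A schedule effect scales the generative parameters while a labelled
#' condition interval is active. The profile ramps from no effect to the full
#' multiplier either as a step or exponentially after an onset latency:
#' `m(t) = 1 + (m_full - 1) * (1 - exp(-(t - t_on - latency)/tau))` for
#' `t > t_on + latency` (and 1 before), clock restarting at each interval.
#'
#' Constructors for the three published conditions:
#' * `effect_5ht()`: serotonin wash-in; no effect for a 5-minute latency,
#'   then exponential approach with a 300 s time constant (about 95 % of the
#'   full effect 15 minutes after application). The default multipliers move
#'   the basal on-chip phenotype to the serotonin-stimulated one.
#' * `effect_ethanol()`: rapid exponential onset (half-time 1.5 min, within
#'   the published "under 2 minutes"); lowers frequency, lengthens pumps,
#'   suppresses P waves and reduces the E amplitude. Magnitudes are
#'   illustrative defaults (the source figures are not tabulated).
#' * `effect_light()`: step multipliers active only inside `light_on`
#'   intervals: faster pumping, shorter pumps.
#'
#' @param condition Condition label the effect binds to.
#' @param freq_mult,dur_mult,p_rate_mult,e_spike_mult Full-effect multipliers
#'   (> 0) for pump frequency, duration, P-wave intensity and the E/e
#'   excitation amplitudes.
#' @param onset_latency Seconds after the interval start before any effect.
#' @param time_constant Exponential time constant in seconds; `0` gives a
#'   step profile.
#' @return An object of class `schedule_effect`.
#' @export
schedule_effect <- function(condition, freq_mult = 1, dur_mult = 1,
                            p_rate_mult = 1, e_spike_mult = 1,
                            onset_latency = 0, time_constant = 0) {
  if (!condition %in% SCHEDULE_LABELS)
    stopf("condition must be one of: %s", paste(SCHEDULE_LABELS, collapse = ", "))
  m <- c(freq_mult, dur_mult, p_rate_mult, e_spike_mult)
  if (any(m <= 0)) stopf("all multipliers must be positive")
  structure(list(condition = condition, freq_mult = freq_mult, dur_mult = dur_mult,
                 p_rate_mult = p_rate_mult, e_spike_mult = e_spike_mult,
                 onset_latency = onset_latency, time_constant = time_constant),
            class = "schedule_effect")
}

#' @rdname schedule_effect
#' @export
effect_5ht <- function(freq_mult = 3.467 / 0.075, dur_mult = 0.101 / 0.116,
                       p_rate_mult = 0.126 / 1.788, e_spike_mult = 1.753 / 0.257) {
  schedule_effect("5HT", freq_mult, dur_mult, p_rate_mult, e_spike_mult,
                  onset_latency = 300, time_constant = 300)
}

#' @rdname schedule_effect
#' @export
effect_ethanol <- function(freq_mult = 0.5, dur_mult = 1.3,
                           p_rate_mult = 0.5, e_spike_mult = 0.7) {
  schedule_effect("ethanol", freq_mult, dur_mult, p_rate_mult, e_spike_mult,
                  onset_latency = 0, time_constant = 90 / log(2))
}

#' @rdname schedule_effect
#' @export
effect_light <- function(freq_mult = 1.5, dur_mult = 0.8) {
  schedule_effect("light_on", freq_mult, dur_mult, 1, 1,
                  onset_latency = 0, time_constant = 0)
}

# multiplier value of one effect at time t given the trace schedule
effect_multipliers <- function(effects, schedule, t) {
  m <- c(freq = 1, dur = 1, p = 1, e_spike = 1)
  if (is.null(effects) || is.null(schedule) || nrow(schedule) == 0L) return(m)
  for (eff in effects) {
    rows <- schedule[schedule$condition == eff$condition, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      if (t < rows$start_s[i] || t >= rows$end_s[i]) next
      dt <- t - rows$start_s[i] - eff$onset_latency
      frac <- if (dt <= 0) 0
              else if (eff$time_constant <= 0) 1
              else 1 - exp(-dt / eff$time_constant)
      m["freq"] <- m["freq"] * (1 + (eff$freq_mult - 1) * frac)
      m["dur"] <- m["dur"] * (1 + (eff$dur_mult - 1) * frac)
      m["p"] <- m["p"] * (1 + (eff$p_rate_mult - 1) * frac)
      m["e_spike"] <- m["e_spike"] * (1 + (eff$e_spike_mult - 1) * frac)
    }
  }
  m
}
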
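# Generative model for EPG traces with per-transient ground truth.
#
# The simulator is phenomenological, not biophysical: each pump is a
# stereotyped complex of five transient bumps (e, E, P..., R, r) whose
# timing and amplitudes are drawn from a phenotype preset, placed by a
# gamma renewal process and rendered onto a uniform sample grid, plus
# sub-hertz sinusoidal baseline drift and white Gaussian noise.

#' Draw a per-worm latent parameter set
#'
#' Worm-level means are the preset means scaled by independent lognormal
#' multipliers with unit mean and coefficient of variation `worm_cv`,
#' emulating between-worm variability. With `worm_cv = 0` the worm means
#' equal the preset means exactly.
#'
#' @param preset An [epg_preset()].
#' @param seed Integer seed; a fixed seed gives an identical parameter set.
#' @return A list with worm-level `freq`, `dur`, `p_rate`, `amp_pp`,
#'   `e_amp`, `re_ratio` plus the preset's within-worm cv values.
#' @export
draw_worm <- function(preset, seed) {
  stopifnot(inherits(preset, "epg_preset"))
  with_seed(seed, {
    m <- rlnorm_mult(6L, preset$worm_cv)
    list(freq = preset$freq_mean * m[1L],
         dur = preset$dur_mean * m[2L],
         p_rate = preset$p_rate * m[3L],
         amp_pp = preset$amp_pp_mean * m[4L],
         e_amp = preset$e_amp_mean * m[5L],
         re_ratio = preset$re_ratio_mean * m[6L],
         freq_cv = preset$freq_cv, dur_cv = preset$dur_cv,
         amp_pp_cv = preset$amp_pp_cv)
  })
}

# one transient bump sampled on the trace grid; Gaussian bumps are truncated
# at +-4 sd so the signal is exactly zero between pumps in noise-free mode
render_transient <- function(samples, rate, t0, tc, amp, width, shape) {
  if (amp == 0) return(samples)
  if (shape == "gaussian") {
    sd <- width / (2 * sqrt(2 * log(2)))
    half <- 4 * sd
    i0 <- max(1L, as.integer(ceiling((tc - half - t0) * rate)) + 1L)
    i1 <- min(length(samples), as.integer(floor((tc + half - t0) * rate)) + 1L)
    if (i1 < i0) return(samples)
    tt <- t0 + (i0:i1 - 1L) / rate
    samples[i0:i1] <- samples[i0:i1] + amp * exp(-(tt - tc)^2 / (2 * sd^2))
  } else {
    # biexponential: rise tau = width/5, decay tau = width/1.5, peak at tc
    tr <- width / 5
    td <- width / 1.5
    tpk <- tr * td / (td - tr) * log(td / tr)
    half <- 6 * td
    i0 <- max(1L, as.integer(ceiling((tc - tpk - t0) * rate)) + 1L)
    i1 <- min(length(samples), as.integer(floor((tc - tpk + half - t0) * rate)) + 1L)
    if (i1 < i0) return(samples)
    tt <- t0 + (i0:i1 - 1L) / rate - (tc - tpk)
    v <- exp(-tt / td) - exp(-tt / tr)
    vpk <- exp(-tpk / td) - exp(-tpk / tr)
    samples[i0:i1] <- samples[i0:i1] + amp * v / vpk
  }
  samples
}

# extent of one pump on the time axis (first to last rendered sample)
pump_extent <- function(ev, kernel) {
  sd_of <- function(w) w / (2 * sqrt(2 * log(2)))
  c(min(ev$time_s) - 4 * sd_of(kernel$e_width),
    max(ev$time_s) + 4 * sd_of(kernel$r_width))
}

#' Generate a synthetic EPG trace with ground truth
#'
#' Pump onsets follow a refractory renewal process: each E-to-E interval is
#' a hard minimum separation (the previous pump's rendered extent plus a
#' short silent gap) plus a gamma-distributed excess, with the interval mean
#' kept at exactly `1/frequency` (and dispersion set by `freq_cv`), so pump
#' complexes never overlap and the long-run pump rate converges to the
#' preset frequency even at serotonin-stimulated rates. Each pump
#' renders: a small positive e spike leading E, the large positive E spike,
#' a Poisson-count set of negative P waves placed uniformly in the plateau
#' between the E and R transients with at least `2 * P_width` mutual
#' separation, the large negative R spike (amplitude `re_ratio` times E) and
#' the small negative r spike. Additive interference is a sum of three
#' sub-0.3 Hz sinusoids (baseline drift, removable by [highpass()]) and
#' white Gaussian noise with `sigma = amp_pp / snr`.
#'
#' @param preset An [epg_preset()] or preset name.
#' @param duration Recording length in seconds.
#' @param rate Sampling rate in Hz (default 2000: EPG transients last
#'   10-100 ms, so 2 kHz resolves the narrowest with ~16 samples).
#' @param snr Peak-to-peak amplitude over noise sigma; `Inf` disables noise.
#'   Default 50, the calibration at which all five phases are resolvable
#'   (see the methods vignette).
#' @param seed Integer seed; fixed seed gives a bit-identical trace and
#'   ground truth.
#' @param kernel A [epg_kernel()] describing transient morphology.
#' @param schedule Optional [epg_schedule()] of condition intervals.
#' @param effects Optional list of [schedule_effect()]s applied while their
#'   condition is active.
#' @param drift Logical; render baseline drift (default TRUE).
#' @param worm Optional latent parameter set from [draw_worm()]; by default
#'   a worm is drawn from the preset using `seed`.
#' @param worm_id Identifier recorded in the ground truth.
#' @param t0 Start time in seconds.
#' @return A list with elements `trace` (an [epg_trace()]) and `truth`
#'   (a data frame with columns worm_id, pump_index, event_type, time_s,
#'   amplitude_mV; one row per placed transient).
#' @export
generate_trace <- function(preset, duration, rate = 2000, snr = 50,
                           seed = 1L, kernel = epg_kernel(),
                           schedule = NULL, effects = NULL, drift = TRUE,
                           worm = NULL, worm_id = "worm1", t0 = 0) {
  if (is.character(preset)) preset <- epg_preset(preset)
  stopifnot(inherits(preset, "epg_preset"), inherits(kernel, "pump_kernel"))
  if (duration <= 0) stopf("duration must be positive")
  if (snr <= 0) stopf("snr must be positive")
  check_kernel_vs_duration(kernel, preset$dur_mean)
  if (!is.null(schedule)) schedule <- validate_schedule(schedule, t0, duration)

  seeds <- derive_seeds(seed, 2L)
  if (is.null(worm)) worm <- draw_worm(preset, seeds[1L])

  with_seed(seeds[2L], {
    n <- as.integer(round(duration * rate))
    samples <- numeric(n)
    truth <- list()
    pump_i <- 0L
    sd_e <- kernel$e_width / (2 * sqrt(2 * log(2)))
    gap_min <- 0.005  # minimum silent gap between rendered pump extents

    if (worm$freq > 0) {
      shape_g <- if (worm$freq_cv > 0) 1 / worm$freq_cv^2 else Inf
      t_E <- t0
      prev_end <- -Inf
      sd_r <- kernel$r_width / (2 * sqrt(2 * log(2)))
      prev_dmin <- kernel$e_lead + 4 * sd_e + gap_min   # before the first pump
      repeat {
        mult <- effect_multipliers(effects, schedule, t_E)
        f_now <- worm$freq * mult[["freq"]]
        if (f_now <= 1e-9) break
        # refractory renewal: a hard minimum separation (the previous pump's
        # rendered extent plus a short silent gap) plus a gamma-distributed
        # excess whose mean keeps the overall E-to-E interval at exactly
        # 1/frequency; pumps can then never overlap and the long-run pump
        # rate converges to the preset frequency (pure thinning of a gamma
        # renewal process loses ~10 % of pumps at serotonin-stimulated rates)
        mean_iv <- 1 / f_now
        excess <- max(mean_iv - prev_dmin, 0.2 * mean_iv)
        iv <- prev_dmin + (if (is.finite(shape_g))
                stats::rgamma(1L, shape = shape_g, scale = excess / shape_g)
              else excess)
        t_E <- t_E + iv
        mult <- effect_multipliers(effects, schedule, t_E)
        dur_i <- worm$dur * mult[["dur"]] * rlnorm_mult(1L, worm$dur_cv)
        t_R <- t_E + dur_i
        t_r <- t_R + kernel$r_lag
        t_e <- t_E - kernel$e_lead
        if (t_r + 4 * kernel$r_width > t0 + duration) break
        start_i <- t_e - 4 * sd_e
        prev_dmin <- dur_i + kernel$r_lag + 4 * sd_r + kernel$e_lead + 4 * sd_e + gap_min
        if (start_i < prev_end + gap_min || start_i < t0) next  # safety net; rare

        amp_i <- worm$amp_pp * rlnorm_mult(1L, worm$amp_pp_cv)
        re_i <- worm$re_ratio * rlnorm_mult(1L, worm$amp_pp_cv / 2)
        a_E <- amp_i / (1 + re_i) * mult[["e_spike"]]
        a_R <- -amp_i * re_i / (1 + re_i)
        a_e <- worm$e_amp * mult[["e_spike"]] * rlnorm_mult(1L, worm$amp_pp_cv)
        a_r <- -kernel$r_rel_amp * abs(a_R)

        # P waves: uniform in the plateau, clear of the E and R transients,
        # with >= 2 * P_width mutual separation
        p_lambda <- worm$p_rate * mult[["p"]]
        lo <- t_E + kernel$E_width + kernel$P_width
        hi <- t_R - kernel$E_width - kernel$P_width
        sep <- 2 * kernel$P_width
        span <- hi - lo
        k <- if (p_lambda > 0 && span > 0) stats::rpois(1L, p_lambda) else 0L
        cap <- if (span > 0) floor(span / sep) + 1L else 0L
        k <- min(k, cap)
        t_P <- if (k > 0L) {
          u <- sort(stats::runif(k, 0, span - (k - 1L) * sep))
          lo + u + (seq_len(k) - 1L) * sep
        } else numeric(0)
        a_P <- if (k > 0L) -kernel$p_rel_amp * abs(amp_i / (1 + re_i)) *
                 rlnorm_mult(k, worm$amp_pp_cv) else numeric(0)

        pump_i <- pump_i + 1L
        ev <- data.frame(
          worm_id = worm_id, pump_index = pump_i,
          event_type = c(if (a_e > 0) "e", "E", rep("P", k), "R",
                         if (abs(a_r) > 0) "r"),
          time_s = c(if (a_e > 0) t_e, t_E, t_P, t_R, if (abs(a_r) > 0) t_r),
          amplitude_mV = c(if (a_e > 0) a_e, a_E, a_P, a_R, if (abs(a_r) > 0) a_r),
          stringsAsFactors = FALSE)
        truth[[pump_i]] <- ev
        for (j in seq_len(nrow(ev))) {
          w <- switch(ev$event_type[j], e = kernel$e_width, E = kernel$E_width,
                      P = kernel$P_width, R = kernel$E_width, r = kernel$r_width)
          samples <- render_transient(samples, rate, t0, ev$time_s[j],
                                      ev$amplitude_mV[j], w, kernel$shape)
        }
        prev_end <- pump_extent(ev, kernel)[2L]
      }
    }

    if (drift) {
      tt <- t0 + (seq_len(n) - 1L) / rate
      for (d in 1:3) {
        f_d <- stats::runif(1L, 0.02, 0.3)
        a_d <- 0.2 * worm$amp_pp / 3 * stats::runif(1L, 0.5, 1)
        ph <- stats::runif(1L, 0, 2 * pi)
        samples <- samples + a_d * sin(2 * pi * f_d * tt + ph)
      }
    }
    if (is.finite(snr)) samples <- samples + stats::rnorm(n, sd = worm$amp_pp / snr)

    truth <- if (length(truth)) do.call(rbind, truth)
             else data.frame(worm_id = character(0), pump_index = integer(0),
                             event_type = character(0), time_s = numeric(0),
                             amplitude_mV = numeric(0), stringsAsFactors = FALSE)
    list(trace = epg_trace(samples, rate, t0 = t0, label = preset$name,
                           schedule = schedule),
         truth = truth)
  })
}

#' Ground truth pump summary
#'
#' Collapses a long-format ground truth table (one row per transient) to one
#' row per pump with `t_E`, `t_R`, `n_P`, the true duration and amplitudes.
#'
#' @param truth Ground truth data frame from [generate_trace()].
#' @return A data frame with one row per pump.
#' @export
truth_pumps <- function(truth) {
  if (nrow(truth) == 0L)
    return(data.frame(worm_id = character(0), pump_index = integer(0),
                      t_E = numeric(0), t_R = numeric(0), n_P = integer(0),
                      a_E = numeric(0), a_R = numeric(0), duration = numeric(0)))
  sp <- split(truth, truth$pump_index)
  out <- do.call(rbind, lapply(sp, function(g) {
    data.frame(worm_id = g$worm_id[1L], pump_index = g$pump_index[1L],
               t_E = g$time_s[g$event_type == "E"][1L],
               t_R = g$time_s[g$event_type == "R"][1L],
               n_P = sum(g$event_type == "P"),
               a_E = g$amplitude_mV[g$event_type == "E"][1L],
               a_R = g$amplitude_mV[g$event_type == "R"][1L],
               stringsAsFactors = FALSE)
  }))
  out$duration <- out$t_R - out$t_E
  out <- out[order(out$t_E), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate a tail-first (wrong orientation) recording
#'
#' Emulates the signal from a worm that entered the trap tail first:
#' pump-rate-matched monophasic positive blips at about a quarter of the
#' head-recording amplitude, with none of the e/P/R/r structure of a true
#' EPG. Used to exercise the orientation gate.
#'
#' @param duration,rate,snr,seed,t0 As in [generate_trace()].
#' @return An [epg_trace()].
#' @export
generate_tail_trace <- function(duration, rate = 2000, snr = 50, seed = 1L, t0 = 0) {
  preset <- epg_preset("tail")
  seeds <- derive_seeds(seed, 2L)
  worm <- draw_worm(preset, seeds[1L])
  with_seed(seeds[2L], {
    n <- as.integer(round(duration * rate))
    samples <- numeric(n)
    shape_g <- 1 / worm$freq_cv^2
    t_c <- t0
    width <- 0.030  # one broad featureless blip per pump
    repeat {
      t_c <- t_c + stats::rgamma(1L, shape = shape_g, scale = 1 / (worm$freq * shape_g))
      if (t_c + 4 * width > t0 + duration) break
      amp <- worm$amp_pp * rlnorm_mult(1L, worm$amp_pp_cv)
      samples <- render_transient(samples, rate, t0, t_c, amp, width, "gaussian")
    }
    if (is.finite(snr)) samples <- samples + stats::rnorm(n, sd = worm$amp_pp / snr)
    epg_trace(samples, rate, t0 = t0, label = "tail")
  })
}

#' Generate a cohort of independent worms
#'
#' One independent simulated worm per animal, with true labels retained for
#' screening validation and worm order shuffled deterministically by seed.
#'
#' @param composition Named integer vector of counts per preset, e.g.
#'   `c(wt_basal_chip = 7, eat4_chip = 3)`. Use preset name `"tail"` for
#'   wrong-orientation traces.
#' @param duration Seconds of recording per worm.
#' @param rate,snr,kernel As in [generate_trace()].
#' @param seed Integer seed for the whole cohort.
#' @return A list with one element per worm: `trace`, `truth` (NULL for tail
#'   traces), `true_label` (the preset name) and `worm_id`.
#' @export
generate_cohort <- function(composition, duration, rate = 2000, snr = 50,
                            seed = 1L, kernel = epg_kernel()) {
  if (length(composition) == 0L || sum(composition) == 0L)
    stopf("empty cohort composition")
  if (is.null(names(composition)) || any(!nzchar(names(composition))))
    stopf("composition must be a named vector of preset counts")
  labels <- rep(names(composition), times = as.integer(composition))
  n <- length(labels)
  seeds <- derive_seeds(seed, n + 1L)
  order_idx <- with_seed(seeds[n + 1L], sample.int(n))
  labels <- labels[order_idx]
  lapply(seq_len(n), function(i) {
    wid <- sprintf("worm%02d", i)
    if (labels[i] == "tail") {
      list(trace = generate_tail_trace(duration, rate, snr, seed = seeds[i], t0 = 0),
           truth = NULL, true_label = "tail", worm_id = wid)
    } else {
      sim <- generate_trace(labels[i], duration, rate, snr, seed = seeds[i],
                            kernel = kernel, worm_id = wid)
      list(trace = sim$trace, truth = sim$truth, true_label = labels[i],
           worm_id = wid)
    }
  })
}

#' Write / read a ground truth table as TSV
#'
#' Long format with columns worm_id, pump_index, event_type, time_s,
#' amplitude_mV.
#'
#' @param truth Ground truth data frame.
#' @param path File path.
#' @return `read_truth()` returns the data frame; `write_truth()` its path,
#'   invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
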
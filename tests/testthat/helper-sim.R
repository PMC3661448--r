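# Shared fixtures, all generated in code. Unit tests run at 1 kHz and short
# durations to stay fast; the acceptance suite uses the full 2 kHz scale.

quiet_detect <- function(trace, ...) suppressWarnings(detect_pumps(trace, ...))

# hand-built event table for exact-arithmetic parameter tests
make_events <- function(t_E, a_E, t_R, a_R, t_P = NULL, a_P = NULL,
                        t_e = NA_real_, a_e = NA_real_,
                        t_r = NA_real_, a_r = NA_real_,
                        analyzed_s = 60, worm_id = "w") {
  n <- length(t_E)
  rec <- function(v) rep_len(v, n)
  ev <- data.frame(worm_id = worm_id, pump_index = seq_len(n),
                   t_e = rec(t_e), a_e = rec(a_e),
                   t_E = t_E, a_E = a_E,
                   n_P = if (is.null(t_P)) 0L else lengths(t_P),
                   t_R = t_R, a_R = a_R,
                   t_r = rec(t_r), a_r = rec(a_r),
                   flags = "complete", stringsAsFactors = FALSE)
  ev$t_P <- if (is.null(t_P)) replicate(n, numeric(0), simplify = FALSE) else t_P
  ev$a_P <- if (is.null(a_P)) replicate(n, numeric(0), simplify = FALSE) else a_P
  structure(ev, class = c("epg_events", "data.frame"),
            sigma = 0.05, analyzed_s = analyzed_s, rate = 1000, t0 = 0,
            worm_id = worm_id)
}

# a preset object with overridden fields (for degenerate-case tests)
preset_with <- function(base = "wt_basal_chip", ...) {
  p <- epg_preset(base)
  over <- list(...)
  for (nm in names(over)) p[[nm]] <- over[[nm]]
  epgtools:::validate_preset(unclass(p))
}
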
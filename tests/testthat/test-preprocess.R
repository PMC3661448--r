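# Bessel high-pass, baseline and SNR estimation

rate <- 2000

test_that("designed response hits the prescribed attenuation and passband", {
  spec <- filter_spec()
  # frozen design values, cross-checked against an independent filter-design
  # implementation during development (agreement to 6 significant figures)
  expect_equal(highpass_response(spec, 0.5, rate), 10^(-30 / 20), tolerance = 1e-6)
  expect_equal(highpass_response(spec, 10, rate), 0.990278, tolerance = 1e-4)
  expect_equal(highpass_response(spec, 0.05, rate), 3.5171e-6, tolerance = 1e-3)
  # attenuation within 0.5 dB of configured
  att_db <- -20 * log10(highpass_response(spec, spec$cutoff, rate))
  expect_lt(abs(att_db - 30), 0.5)
  # conventional -3 dB reading is one configuration away
  spec3 <- filter_spec(attenuation_db = 3)
  expect_equal(highpass_response(spec3, 0.5, rate), 10^(-3 / 20), tolerance = 1e-6)
})

test_that("DC is rejected to numerical zero", {
  tr <- epg_trace(rep(5, 10 * rate), rate)
  out <- highpass(tr)
  core <- out$samples[(2 * rate):(8 * rate)]
  expect_lt(max(abs(core)), 1e-6)
})

test_that("stopband and passband sinusoids behave as designed", {
  tt <- (0:(60 * rate - 1)) / rate
  slow <- epg_trace(sin(2 * pi * 0.05 * tt), rate)
  out <- highpass(slow)$samples[(10 * rate):(50 * rate)]
  expect_lt(max(abs(out)), 0.05)
  fast <- epg_trace(sin(2 * pi * 10 * tt[1:(10 * rate)]), rate)
  outf <- highpass(fast)$samples[(2 * rate):(8 * rate)]
  amp <- diff(range(outf)) / 2
  expect_gte(amp, 0.97)
  expect_lte(amp, 1.0)
})

test_that("highpass is linear and errors on cutoff above Nyquist", {
  set.seed(42)
  x <- rnorm(4000); y <- rnorm(4000)
  hx <- highpass(epg_trace(x, rate))$samples
  hy <- highpass(epg_trace(y, rate))$samples
  hxy <- highpass(epg_trace(2 * x - 3 * y, rate))$samples
  expect_equal(hxy, 2 * hx - 3 * hy, tolerance = 1e-9)
  expect_error(highpass(epg_trace(x, 0.8), filter_spec(cutoff = 0.5)), "Nyquist")
  expect_error(filter_spec(order = 12), "order")
})

test_that("highpass removes the simulator's drift", {
  sim <- generate_trace("wt_basal_chip", duration = 120, rate = 1000,
                        snr = Inf, drift = TRUE, seed = 9)
  filtered <- highpass(sim$trace)
  tp <- truth_pumps(sim$truth)
  # inter-pump samples, away from every pump complex
  tt <- trace_times(filtered)
  near <- Reduce(`|`, lapply(seq_len(nrow(tp)), function(k)
    tt > tp$t_E[k] - 0.15 & tt < tp$t_R[k] + 0.15))
  gap <- filtered$samples[!near & tt > 5 & tt < 115]
  expect_lt(abs(mean(gap)), 0.02 * 4.410)
})

test_that("estimate_baseline is a robust running median", {
  tr <- epg_trace(rep(0.2, 5000), 1000)
  expect_equal(estimate_baseline(tr), rep(0.2, 5000))
  spiked <- rep(0.2, 5000); spiked[2500:2509] <- 8
  bl <- estimate_baseline(epg_trace(spiked, 1000))
  expect_equal(bl[2500:2509], rep(0.2, 10))
  ramp <- seq(0, 5, length.out = 5000)
  blr <- estimate_baseline(epg_trace(ramp, 1000))
  mid <- 1500:3500
  expect_lt(max(abs(blr[mid] - ramp[mid])), diff(ramp)[1] + 1e-12)
  expect_error(estimate_baseline(epg_trace(rnorm(100), 1000), window = 0.001),
               "shorter than 3 samples")
})

test_that("estimate_snr matches a constructed signal and handles edge cases", {
  sim <- generate_trace(preset_with(amp_pp_mean = 4.41, worm_cv = 0, amp_pp_cv = 0),
                        duration = 300, rate = 1000, snr = 4.41 / 0.5, seed = 4,
                        drift = FALSE)
  tr <- sim$trace
  ev <- quiet_detect(tr)
  snr <- estimate_snr(tr, ev)
  expect_gte(snr, 7.9)
  expect_lte(snr, 9.8)
  # noise-free -> infinite
  simc <- generate_trace("wt_basal_chip", duration = 60, rate = 1000,
                         snr = Inf, drift = FALSE, seed = 4)
  expect_identical(estimate_snr(simc$trace, quiet_detect(simc$trace)), Inf)
  # pure noise with an empty supplied event table -> error
  noise <- epg_trace(rnorm(20000, sd = 0.1), 1000)
  empty <- quiet_detect(epg_trace(rep(0, 2000), 1000))
  expect_error(estimate_snr(noise, empty), "no pumps")
})

test_that("estimate_snr recovers the configured simulator snr within 20 %", {
  for (s in c(4, 8, 20)) {
    sim <- generate_trace("wt_5ht_chip", duration = 60, rate = 1000,
                          snr = s, seed = 11)
    tr <- highpass(sim$trace)
    tp <- truth_pumps(sim$truth)
    ev <- make_events(tp$t_E, tp$a_E, tp$t_R, tp$a_R, analyzed_s = 60)
    attr(ev, "rate") <- 1000
    est <- estimate_snr(tr, ev)
    expect_gte(est, 0.8 * s)
    expect_lte(est, 1.2 * s)
  }
})
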
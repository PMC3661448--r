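# generative model: presets, worm draws, traces, ground truth, cohorts

test_that("shipped presets load and carry the published NeuroChip phenotypes", {
  expect_setequal(epg_presets(),
                  c("wt_basal_chip", "wt_5ht_chip", "wt_basal_conventional",
                    "wt_5ht_conventional", "eat4_chip", "eat4_conventional", "tail"))
  wt <- epg_preset("wt_basal_chip")
  expect_equal(c(wt$freq_mean, wt$dur_mean, wt$p_rate, wt$amp_pp_mean, wt$e_amp_mean),
               c(0.075, 0.116, 1.788, 4.410, 0.257))
  ht <- epg_preset("wt_5ht_chip")
  expect_equal(c(ht$freq_mean, ht$dur_mean, ht$p_rate, ht$amp_pp_mean, ht$e_amp_mean),
               c(3.467, 0.101, 0.126, 8.370, 1.753))
  e4 <- epg_preset("eat4_chip")
  expect_equal(c(e4$freq_mean, e4$dur_mean, e4$p_rate, e4$re_ratio_mean),
               c(0.090, 0.172, 0.103, 1.491))
  expect_error(epg_preset("nonsense"), "wt_basal_chip")
})

test_that("draw_worm: degenerate spread, determinism and Monte-Carlo cv", {
  p0 <- preset_with(worm_cv = 0)
  w <- draw_worm(p0, 1)
  expect_equal(w$freq, p0$freq_mean)
  expect_equal(w$amp_pp, p0$amp_pp_mean)
  p <- epg_preset("wt_basal_chip")
  expect_identical(draw_worm(p, 7), draw_worm(p, 7))
  freqs <- vapply(seq_len(1000), function(s) draw_worm(p, s)$freq, numeric(1))
  cv <- sd(freqs) / mean(freqs)
  expect_gte(cv, 0.08)
  expect_lte(cv, 0.12)
  expect_equal(mean(freqs) / p$freq_mean, 1, tolerance = 0.02)
})

test_that("fixed seed gives bit-identical trace and ground truth", {
  a <- generate_trace("wt_5ht_chip", duration = 10, rate = 1000, seed = 3)
  b <- generate_trace("wt_5ht_chip", duration = 10, rate = 1000, seed = 3)
  expect_identical(a$trace$samples, b$trace$samples)
  expect_identical(a$truth, b$truth)
  c <- generate_trace("wt_5ht_chip", duration = 10, rate = 1000, seed = 4)
  expect_false(identical(a$trace$samples, c$trace$samples))
})

test_that("ground truth obeys the phase ordering invariant on every pump", {
  for (preset in c("wt_basal_chip", "wt_5ht_chip", "eat4_chip")) {
    sim <- generate_trace(preset, duration = if (preset == "wt_5ht_chip") 30 else 300,
                          rate = 1000, seed = 5)
    sp <- split(sim$truth, sim$truth$pump_index)
    for (g in sp) {
      t_of <- function(ty) g$time_s[g$event_type == ty]
      expect_true(t_of("e") < t_of("E"))
      expect_true(all(t_of("P") > t_of("E")) && all(t_of("P") < t_of("R")))
      expect_true(t_of("E") < t_of("R") && t_of("R") < t_of("r"))
      expect_true(g$amplitude_mV[g$event_type == "E"] > 0)
      expect_true(all(g$amplitude_mV[g$event_type %in% c("P", "R", "r")] < 0))
    }
    tp <- truth_pumps(sim$truth)
    if (nrow(tp) > 1) expect_true(all(diff(tp$t_E) > 0))
  }
})

test_that("noise- and drift-free signal is exactly zero between pumps", {
  sim <- generate_trace("wt_basal_chip", duration = 120, rate = 1000,
                        snr = Inf, drift = FALSE, seed = 6)
  tp <- truth_pumps(sim$truth)
  tt <- trace_times(sim$trace)
  inside <- Reduce(`|`, lapply(seq_len(nrow(tp)), function(k)
    tt >= tp$t_E[k] - 0.08 & tt <= tp$t_R[k] + 0.08))
  expect_true(all(sim$trace$samples[!inside] == 0))
  expect_gt(sum(!inside), 0.5 * length(tt))
})

test_that("noise-free local extrema match ground truth to within one sample (brute-force oracle)", {
  rate <- 2000
  sim <- generate_trace("wt_basal_chip", duration = 80, rate = rate,
                        snr = Inf, drift = FALSE, seed = 8)
  x <- sim$trace$samples
  for (k in unique(sim$truth$pump_index)) {
    g <- sim$truth[sim$truth$pump_index == k, ]
    for (j in seq_len(nrow(g))) {
      i0 <- round(g$time_s[j] * rate) + 1
      w <- (i0 - 6):(i0 + 6)
      i_ext <- if (g$amplitude_mV[j] > 0) w[which.max(x[w])] else w[which.min(x[w])]
      expect_lte(abs(i_ext - 1 - g$time_s[j] * rate), 1)
    }
  }
})

test_that("zero frequency gives a flat trace and empty ground truth", {
  p0 <- preset_with(freq_mean = 0)
  sim <- generate_trace(p0, duration = 20, rate = 1000, snr = Inf, drift = FALSE, seed = 2)
  expect_equal(nrow(sim$truth), 0L)
  expect_true(all(sim$trace$samples == 0))
})

test_that("serotonin-stimulated pump count is consistent with the published rate", {
  sim <- generate_trace("wt_5ht_chip", duration = 120, rate = 1000, seed = 12)
  n <- nrow(truth_pumps(sim$truth))
  expected <- 3.467 * 120
  # one worm: allow worm-level cv (0.10) plus counting noise
  expect_lt(abs(n - expected), 4 * sqrt(expected) + 2.5 * 0.10 * expected)
})

test_that("long-run frequency and P rate converge to the preset (worm_cv 0)", {
  p <- preset_with("wt_5ht_chip", worm_cv = 0)
  sim <- generate_trace(p, duration = 200, rate = 1000, snr = Inf, drift = FALSE, seed = 13)
  tp <- truth_pumps(sim$truth)
  expect_gt(nrow(tp), 500)
  expect_lt(abs(nrow(tp) / 200 - p$freq_mean) / p$freq_mean, 0.05)
  pb <- preset_with("wt_basal_chip", worm_cv = 0, freq_mean = 1.5)
  simb <- generate_trace(pb, duration = 400, rate = 1000, snr = Inf, drift = FALSE, seed = 14)
  tpb <- truth_pumps(simb$truth)
  expect_gt(nrow(tpb), 500)
  expect_lt(abs(mean(tpb$n_P) - pb$p_rate) / pb$p_rate, 0.10)
})

test_that("kernel incompatible with the pump duration fails before synthesis", {
  p <- preset_with(dur_mean = 0.015)
  expect_error(generate_trace(p, duration = 10, seed = 1), "incompatible")
  expect_error(epg_kernel(e_lead = 0.003), "e_lead")
  expect_error(epg_kernel(p_rel_amp = 1.5), "p_rel_amp")
})

test_that("tail traces are small, monophasic and deterministic", {
  tr <- generate_tail_trace(120, rate = 1000, seed = 3)
  expect_lt(diff(range(tr$samples)), 0.40 * 4.410)
  trc <- generate_tail_trace(60, rate = 1000, snr = Inf, seed = 3)
  expect_gte(min(trc$samples), 0)   # no negative transients at all
  expect_identical(generate_tail_trace(30, rate = 1000, seed = 5)$samples,
                   generate_tail_trace(30, rate = 1000, seed = 5)$samples)
})

test_that("cohorts have the requested composition, labels and seeded shuffle", {
  coh <- generate_cohort(c(wt_basal_chip = 7, eat4_chip = 3), duration = 5,
                         rate = 500, seed = 1)
  expect_length(coh, 10L)
  labs <- vapply(coh, `[[`, character(1), "true_label")
  expect_equal(sum(labs == "eat4_chip"), 3L)
  one <- generate_cohort(c(wt_basal_chip = 0, eat4_chip = 1), duration = 5,
                         rate = 500, seed = 1)
  expect_length(one, 1L)
  coh2 <- generate_cohort(c(wt_basal_chip = 7, eat4_chip = 3), duration = 5,
                          rate = 500, seed = 2)
  labs2 <- vapply(coh2, `[[`, character(1), "true_label")
  expect_equal(sort(labs), sort(labs2))
  expect_false(identical(labs, labs2))
  expect_error(generate_cohort(c(wt_basal_chip = 0), duration = 5, seed = 1), "empty")
})

test_that("serotonin wash-in raises late-trace pump rate (schedule effects)", {
  sched <- epg_schedule(0, 1500, "5HT")
  sim <- generate_trace("wt_basal_chip", duration = 1500, rate = 200,
                        snr = Inf, drift = FALSE, seed = 20,
                        schedule = sched, effects = list(effect_5ht()))
  tp <- truth_pumps(sim$truth)
  early <- sum(tp$t_E < 300) / 300
  late <- sum(tp$t_E > 1200) / 300
  expect_gt(late, 10 * max(early, 1 / 300))
  expect_lt(mean(tp$duration[tp$t_E > 1200]), 0.116)
})

test_that("ground truth TSV round trips", {
  sim <- generate_trace("wt_5ht_chip", duration = 5, rate = 1000, seed = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_truth(sim$truth, f)
  back <- read_truth(f)
  expect_equal(back$time_s, sim$truth$time_s, tolerance = 1e-9)
  expect_equal(back$event_type, sim$truth$event_type)
})
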
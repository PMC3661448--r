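# pump detection and phase labelling

test_that("noise-free detection recovers the ground-truth pump set exactly", {
  rate <- 2000
  sim <- generate_trace("wt_basal_chip", duration = 700, rate = rate,
                        snr = Inf, drift = FALSE, seed = 31)
  tp <- truth_pumps(sim$truth)
  expect_gte(nrow(tp), 50)
  ev <- detect_pumps(sim$trace)
  expect_equal(nrow(ev), nrow(tp))        # precision = recall = 1
  expect_lte(max(abs(ev$t_E - tp$t_E)), 1 / rate)
  expect_lte(max(abs(ev$t_R - tp$t_R)), 1 / rate)
  # P recovery is near-exact; the conservative P gates (depth floor,
  # detrending) may drop the occasional closely spaced P pair
  expect_gte(sum(ev$n_P), 0.95 * sum(tp$n_P))
  expect_lte(sum(ev$n_P), sum(tp$n_P))
})

test_that("eat-4 P rate is recovered over 500 pumps", {
  # published eat-4 on-chip P count is 0.103/pump; tolerance 3 s.e. at 500 pumps
  p <- preset_with("eat4_chip", worm_cv = 0)
  sim <- generate_trace(p, duration = 5600, rate = 1000, seed = 32)
  tr <- highpass(sim$trace)
  ev <- quiet_detect(tr)
  expect_gte(nrow(ev), 450)
  rate_hat <- sum(ev$n_P) / nrow(ev)
  expect_lt(abs(rate_hat - 0.103), 3 * sqrt(0.103 / nrow(ev)))
})

test_that("degenerate traces give empty tables", {
  flat <- epg_trace(rep(0, 5000), 1000)
  expect_equal(nrow(quiet_detect(flat)), 0L)
  short <- epg_trace(rnorm(50), 1000)
  expect_warning(detect_pumps(short), "min_inter_pump")
})

test_that("detection is deterministic and labelled events obey the invariants", {
  sim <- generate_trace("wt_5ht_chip", duration = 60, rate = 1000, seed = 33)
  tr <- highpass(sim$trace)
  ev1 <- detect_pumps(tr)
  ev2 <- detect_pumps(tr)
  expect_identical(as.data.frame(ev1), as.data.frame(ev2))
  expect_gt(nrow(ev1), 100)
  expect_true(all(ev1$t_E < ev1$t_R))
  expect_true(all(ev1$a_E > 0) && all(ev1$a_R < 0))
  for (k in seq_len(nrow(ev1))) {
    tp <- ev1$t_P[[k]]
    expect_true(all(tp > ev1$t_E[k] & tp < ev1$t_R[k]))
    expect_true(all(ev1$a_P[[k]] < 0))
    if (!is.na(ev1$t_e[k])) expect_lt(ev1$t_e[k], ev1$t_E[k])
    if (!is.na(ev1$t_r[k])) expect_gt(ev1$t_r[k], ev1$t_R[k])
  }
  # minimum inter-pump separation
  expect_true(all(ev1$t_E[-1] - ev1$t_R[-nrow(ev1)] >= 0.05))
})

test_that("P-wave count bias stays under 10 % at the SNR-8 device floor", {
  # bias needs averaging: a single 500-pump run carries only ~60 P waves
  # (+-13 % counting noise), so the bias is pooled over three runs
  det <- 0; tru <- 0
  for (s in c(5, 17, 29)) {
    sim <- generate_trace("wt_5ht_chip", duration = 150, rate = 2000,
                          snr = 8, seed = s)
    ev <- quiet_detect(highpass(sim$trace))
    tp <- truth_pumps(sim$truth)
    det <- det + sum(ev$n_P)
    tru <- tru + sum(tp$n_P)
  }
  expect_lt(abs(det / tru - 1), 0.10)
})

test_that("orientation gate separates head from tail recordings", {
  cfg <- detection_config()
  tail <- generate_tail_trace(240, rate = 1000, seed = 34)
  g <- orientation_gate(highpass(tail), cfg)
  expect_equal(g$verdict, "tail_or_bad")
  head_sim <- generate_trace("wt_5ht_chip", duration = 30, rate = 1000, seed = 35)
  gh <- orientation_gate(highpass(head_sim$trace), cfg)
  expect_equal(gh$verdict, "head")
  expect_equal(gh$reason, "ok")
  empty <- epg_trace(rnorm(5000, sd = 0.01), 1000)
  ge <- orientation_gate(empty, cfg)
  expect_equal(ge$verdict, "tail_or_bad")
  expect_equal(ge$reason, "too_few_events")
  # amplitude criterion: a head trace against a much larger reference
  gl <- orientation_gate(highpass(head_sim$trace), cfg, reference_amp = 50)
  expect_equal(gl$verdict, "tail_or_bad")
  expect_equal(gl$reason, "low_amplitude")
})

test_that("event table TSV round trips including P lists and metadata", {
  sim <- generate_trace("wt_basal_chip", duration = 300, rate = 1000, seed = 36)
  ev <- quiet_detect(highpass(sim$trace), worm_id = "wormX")
  expect_gt(nrow(ev), 10)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_events(ev, f)
  back <- read_events(f)
  expect_equal(back$t_E, ev$t_E, tolerance = 1e-8)
  expect_equal(back$n_P, ev$n_P)
  expect_equal(unname(unlist(back$t_P)), unname(unlist(ev$t_P)), tolerance = 1e-8)
  expect_equal(attr(back, "analyzed_s"), attr(ev, "analyzed_s"), tolerance = 1e-8)
  expect_equal(attr(back, "sigma"), attr(ev, "sigma"), tolerance = 1e-6)
})
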
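# per-recording parameters, time courses and group comparison

test_that("compute_parameters does the stated arithmetic", {
  ev <- make_events(t_E = 1.000, a_E = 3.0, t_R = 1.116, a_R = -2.0)
  p <- compute_parameters(ev)
  expect_equal(p$amp_pp, 5.0)
  expect_equal(p$duration, 0.116)
  expect_equal(p$re_ratio, 2 / 3, tolerance = 1e-12)
  expect_equal(p$n_pumps, 1L)
  expect_equal(p$frequency, 1 / 60)
  expect_true(is.na(p$re_interval))
  ev2 <- make_events(t_E = c(9.9, 34.0), a_E = c(3, 3), t_R = c(10.0, 34.1),
                     a_R = c(-2, -2))
  expect_equal(compute_parameters(ev2)$re_interval, 24.0)
})

test_that("empty event table gives an all-missing record", {
  empty <- quiet_detect(epg_trace(rep(0, 2000), 1000))
  p <- compute_parameters(empty)
  expect_equal(p$n_pumps, 0L)
  expect_equal(p$frequency, 0)
  expect_true(is.na(p$duration) && is.na(p$amp_pp) && is.na(p$p_per_pump))
})

test_that("parameters are invariant to pump input order", {
  ev <- make_events(t_E = c(5, 1, 9), a_E = c(3, 2.5, 3.5),
                    t_R = c(5.1, 1.1, 9.1), a_R = c(-3, -2, -4),
                    t_P = list(5.05, numeric(0), 9.06),
                    a_P = list(-1, numeric(0), -1.2))
  shuf <- ev[c(2, 3, 1), ]
  attributes(shuf)[c("sigma", "analyzed_s", "rate", "t0", "worm_id", "class")] <-
    attributes(ev)[c("sigma", "analyzed_s", "rate", "t0", "worm_id", "class")]
  expect_equal(as.data.frame(compute_parameters(ev)),
               as.data.frame(compute_parameters(shuf)))
})

test_that("timecourse bins pumps by E time and conserves counts", {
  ev <- make_events(t_E = seq(5, 95, by = 10), a_E = 3,
                    t_R = seq(5, 95, by = 10) + 0.1, a_R = -3, analyzed_s = 100)
  tc <- frequency_timecourse(ev, 10)
  expect_equal(nrow(tc), 10L)
  expect_equal(tc$frequency, rep(0.1, 10))
  expect_equal(sum(tc$n), 10L)
  empty <- quiet_detect(epg_trace(rep(0, 2000), 1000))
  tce <- frequency_timecourse(empty, 0.5)
  expect_true(all(is.na(tce$duration)))
  expect_true(all(tce$frequency == 0))
  expect_error(frequency_timecourse(ev, -1), "positive")
})

test_that("serotonin wash-in shows in the binned frequency time course", {
  sched <- epg_schedule(0, 1500, "5HT")
  sim <- generate_trace("wt_basal_chip", duration = 1500, rate = 200,
                        snr = Inf, drift = FALSE, seed = 41,
                        schedule = sched, effects = list(effect_5ht()))
  tp <- truth_pumps(sim$truth)
  ev <- make_events(tp$t_E, tp$a_E, tp$t_R, tp$a_R, analyzed_s = 1500)
  tc <- frequency_timecourse(ev, 100)
  expect_gt(tc$frequency[nrow(tc)], tc$frequency[1])
})

test_that("epoch summaries capture the optogenetic light response", {
  sched <- epg_schedule(c(0, 120), c(120, 270), c("baseline", "light_on"))
  sim <- generate_trace("wt_5ht_chip", duration = 270, rate = 1000,
                        seed = 42, schedule = sched,
                        effects = list(effect_light()))
  ev <- quiet_detect(highpass(sim$trace))
  tc <- frequency_timecourse(ev, 30)
  es <- epoch_summary(tc, sched)
  expect_equal(nrow(es), 2L)
  light <- es[es$condition == "light_on", ]
  base <- es[es$condition == "baseline", ]
  expect_gt(light$frequency, base$frequency)
  expect_lt(light$duration, base$duration)
  # no-retinal control: no effect applied, difference within noise
  sim0 <- generate_trace("wt_5ht_chip", duration = 270, rate = 1000,
                         seed = 43, schedule = sched)
  tc0 <- frequency_timecourse(quiet_detect(highpass(sim0$trace)), 30)
  es0 <- epoch_summary(tc0, sched)
  per_bin_se <- sd(tc0$frequency) / sqrt(min(es0$n_bins))
  expect_lt(abs(diff(es0$frequency)), 2 * 2 * per_bin_se)
  one <- epoch_summary(tc0, epg_schedule(0, 270, "baseline"))
  expect_equal(nrow(one), 1L)
  expect_warning(epoch_summary(tc0, epg_schedule(10, 12, "custom")), "no complete bin")
})

test_that("compare_groups is a Welch t-test on per-worm values", {
  a <- make_events(t_E = 1, a_E = 3, t_R = 1.1, a_R = -3)
  pa <- compute_parameters(a)
  same <- compare_groups(list(pa, pa, pa), list(pa, pa, pa), "duration")
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_error(compare_groups(list(pa), list(pa, pa), "duration"), "at least 2")
  expect_error(compare_groups(list(pa, pa), list(pa, pa), "bogus"), "unknown metric")
})

test_that("wild-type vs eat-4 duration difference is detected with n = 10 (power)", {
  wt <- epg_preset("wt_basal_chip"); e4 <- epg_preset("eat4_chip")
  n_sig <- 0L
  for (rep in 1:5) {
    # per-worm mean durations: worm-level draw plus within-worm sampling
    # error at ~45 pumps per recording
    set.seed(1000 + rep)
    da <- data.frame(duration = vapply(1:10, function(i)
      draw_worm(wt, 100 * rep + i)$dur + rnorm(1, 0, 0.116 * 0.1 / sqrt(45)), numeric(1)))
    db <- data.frame(duration = vapply(1:10, function(i)
      draw_worm(e4, 900 + 100 * rep + i)$dur + rnorm(1, 0, 0.172 * 0.1 / sqrt(45)), numeric(1)))
    res <- compare_groups(da, db, "duration")
    if (res$p_value < 0.01) n_sig <- n_sig + 1L
  }
  expect_equal(n_sig, 5L)
})

test_that("parameter JSON is written with provenance", {
  a <- compute_parameters(make_events(t_E = 1, a_E = 3, t_R = 1.1, a_R = -3))
  f <- withr::local_tempfile(fileext = ".json")
  write_params(list(a), f, provenance = list(config = "default"))
  rec <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  expect_length(rec, 1L)
  expect_equal(rec[[1]]$amp_pp, 6.0)
  expect_equal(rec[[1]]$provenance$config, "default")
})
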
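# The synthetic session generator: determinism, stimulus scheme, config
# validation, injection mechanics.

test_that("identical configuration and seed give bit-identical sessions", {
  cfg <- session_config("tied_fast", n_cycles = 30, seed = 99)
  s1 <- simulate_session(cfg)
  s2 <- simulate_session(cfg)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$stims, s2$stims)
  expect_identical(s1$emg$signal, s2$emg$signal)
})

test_that("stimulus counts follow the 2-4 cycle gap scheme", {
  cfg <- session_config("tied_slow", n_cycles = 120, seed = 5)
  ev <- simulate_gait_events(cfg)
  st <- simulate_stim_times(cfg, ev)
  expect_gte(nrow(st), 30)
  expect_lte(nrow(st), 60)
  # identical seed, identical list
  expect_identical(st, simulate_stim_times(cfg, ev))
  # inter-stimulus gaps are 2-4 reference cycles
  onsets <- limb_events(ev, cfg$reference_limb)
  onsets <- onsets$time_s[onsets$event == "contact"]
  cyc_of <- findInterval(st$time_s, onsets)
  expect_true(all(diff(cyc_of) >= 2 & diff(cyc_of) <= 4))
})

test_that("stimulus delays populate all ten phase bins uniformly", {
  cfg <- session_config("tied_slow", n_cycles = 360, seed = 13)
  ev <- simulate_gait_events(cfg)
  onsets <- limb_events(ev, cfg$reference_limb)
  onsets <- onsets$time_s[onsets$event == "contact"]
  bins <- integer(0)
  for (sd in 1:100) {
    st <- simulate_stim_times(cfg, ev, seed = 1000 + sd)
    bins <- c(bins, assign_stim_phase(st$time_s, onsets))
  }
  expect_gt(length(bins), 10000)
  prop <- tabulate(bins + 1, nbins = 10) / length(bins)
  expect_true(all(abs(prop - 0.1) < 0.01))
})

test_that("with at least 120 stimuli every bin gets 4+ stimuli in nearly all draws", {
  cfg <- session_config("tied_slow", n_cycles = 360, seed = 13)
  ev <- simulate_gait_events(cfg)
  onsets <- limb_events(ev, cfg$reference_limb)
  onsets <- onsets$time_s[onsets$event == "contact"]
  ok <- vapply(1:40, function(sd) {
    st <- simulate_stim_times(cfg, ev, seed = 2000 + sd)
    b <- assign_stim_phase(st$time_s, onsets)
    nrow(st) >= 100 && all(tabulate(b + 1, nbins = 10) >= 4)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("invalid configurations are rejected", {
  expect_error(session_config(n_cycles = 10), "at least 20")
  expect_error(session_config(emg_sample_rate = 500), "1000 Hz")
  expect_error(session_config(left_speed = -0.4), "positive")
  expect_error(session_config(stim = list(n_pulses = 3, pulse_width_ms = 0.2,
                                          rate_hz = 300, intensity = 1.2,
                                          cycle_gap_range = c(1, 5))),
               "\\[2, 4\\]")
  # stance fraction >= 1 through a broken stance model
  expect_error(session_config(stance_model = list(intercept = 1.2, slope = 0)),
               "outside")
})

test_that("noise-free limit realizes exact alternation and determinism of events", {
  cfg <- session_config("tied_slow", n_cycles = 40, seed = 3, noiseless = TRUE)
  ev <- simulate_gait_events(cfg)
  ca <- coupling_angles(ev, session_belt_speeds_of(cfg), "forelimb", "phase")
  a <- ca$angle[!is.na(ca$angle)]
  expect_true(all(abs(a - 180) < 0.5))
  expect_identical(ev, simulate_gait_events(cfg))
})

test_that("an injected bump changes the channel only inside its latency window", {
  cfg <- session_config("tied_slow", n_cycles = 40, seed = 17, noiseless = TRUE)
  ev <- simulate_gait_events(cfg)
  gt <- default_ground_truth(cfg)
  gt$responses <- tibble::tibble(muscle = "SOL", class = "P1", onset_ms = 10,
                                 duration_ms = 8, profile = list(rep(0.5, 10)))
  one_stim <- tibble::tibble(time_s = 10.0, nerve = "SP", limb = "LH")
  with_bump <- simulate_emg(cfg, ev, one_stim, gt, seed = 1)
  no_stim <- simulate_emg(cfg, ev, one_stim[0, ], gt, seed = 1)
  dvec <- abs(with_bump$signal[, 2] - no_stim$signal[, 2])
  changed <- which(dvec > 1e-12)
  rate <- cfg$emg_sample_rate
  lo <- round((10 + 10 / 1000) * rate) + 1
  hi <- round((10 + 18 / 1000) * rate) + 1
  expect_true(all(changed >= lo & changed <= hi))
  expect_gt(length(changed), 0)
})

test_that("zero-amplitude profiles leave stimulated cycles identical to controls (noise off)", {
  cfg <- session_config("tied_slow", n_cycles = 60, seed = 23, noiseless = TRUE)
  gt <- default_ground_truth(cfg)
  gt$responses$profile <- lapply(gt$responses$profile, function(p) p * 0)
  s <- simulate_session(cfg, gt)
  tr <- reflex_traces(s, "SOL", analysis_config(min_stim_per_bin = 1))
  for (tb in tr$bins) {
    if (is.null(tb$stim_avg)) next
    expect_lt(max(abs(tb$stim_avg - tb$baseline)), 1e-12)
  }
})

test_that("cycle durations order as tied slow > split > tied fast", {
  dur_of <- function(cond) {
    cfg <- session_config(cond, n_cycles = 40, seed = 6)
    kin <- gait_cycles(simulate_gait_events(cfg), session_belt_speeds_of(cfg))
    mean(kin$cycle_duration)
  }
  d <- vapply(c("tied_slow", "split_slow", "tied_fast"), dur_of, numeric(1))
  expect_gt(d["tied_slow"], d["split_slow"])
  expect_gt(d["split_slow"], d["tied_fast"])
})
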
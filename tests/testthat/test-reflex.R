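# Cycle tagging, phase binning, blEMG, detection, classification, net
# values, normalization and modulation indexes.

test_that("cycles are tagged stimulated / excluded / control per the half-open rule", {
  # stim in cycle 3 only: cycle 3 = S, cycle 4 = excluded, cycle 5 = C
  labs <- tag_cycles(0:6, stim_times = 2.5)
  expect_equal(labs, c("control", "control", "stimulated", "excluded",
                       "control", "control"))
  # no stimuli: everything control, including the first cycle
  expect_equal(unique(tag_cycles(0:5, numeric(0))), "control")
  # a stimulus exactly at an onset belongs to the cycle it opens
  labs2 <- tag_cycles(0:4, stim_times = 2)
  expect_equal(labs2, c("control", "control", "stimulated", "excluded"))
})

test_that("stimulus phase bins follow floor(10 * fraction), clamped to bin 9", {
  expect_equal(assign_stim_phase(0.55, c(0, 1)), 5L)
  expect_equal(assign_stim_phase(0, c(0, 1)), 0L)
  expect_equal(assign_stim_phase(0.999, c(0, 1)), 9L)
  expect_error(assign_stim_phase(1.5, c(0, 1)), "outside")
  expect_true(is.na(assign_stim_phase(1.5, c(0, 1), allow_outside = TRUE)))
})

test_that("blEMG of a constant channel is that constant in every bin", {
  s <- noiseless_session()
  s$emg$signal[, 1] <- 0.37
  bl <- build_blemg(s)
  m <- bl$bins$mean[bl$bins$muscle == "SRT"]
  expect_equal(m, rep(0.37, 10), tolerance = 1e-12)
})

test_that("blEMG recovers the generator's envelope and activity window", {
  s <- noiseless_session()
  bl <- build_blemg(s)
  aw <- suppressWarnings(activity_windows(bl))
  gt <- s$ground_truth$activity_windows
  # blEMG bins are in reference-limb cycle time, so compare muscles of the
  # reference limb only (forelimb windows are phase-shifted by the coupling)
  for (ms in gt$muscle[gt$limb == s$config$reference_limb]) {
    got <- aw[aw$muscle == ms, ]
    want <- gt[gt$muscle == ms, ]
    expect_true(got$active)
    # recovered onset/offset within one bin of the injected window
    expect_lte(abs(got$active_start - want$start_frac), 0.1 + 1e-6)
    expect_lte(abs(got$active_end - want$end_frac), 0.1 + 1e-6)
  }
})

test_that("mid-activity window is the activity midpoint +/- 7.5% of the cycle", {
  bl <- structure(list(
    bins = tibble::tibble(muscle = "M", bin = 0:9,
                          mean = c(0, 0, 1, 1, 1, 1, 1, 1, 0, 0)),
    muscles = "M"), class = "blemg_profile")
  aw <- activity_windows(bl)
  expect_equal(aw$active_start, 0.2)
  expect_equal(aw$active_end, 0.8)
  expect_equal(aw$mid_activity_lo, 0.425)
  expect_equal(aw$mid_activity_hi, 0.575)
  # fully silent channel: no active window, warned
  bl0 <- structure(list(
    bins = tibble::tibble(muscle = "M", bin = 0:9, mean = rep(0, 10)),
    muscles = "M"), class = "blemg_profile")
  expect_warning(aw0 <- activity_windows(bl0), "inactive")
  expect_false(aw0$active)
})

test_that("latency classification follows the printed windows and the 18 ms interlimb cap", {
  cfg <- analysis_config()
  expect_equal(classify_response(10, +1, "homonymous", cfg)$class, "P1")
  expect_equal(classify_response(25, -1, "homonymous", cfg)$class, "N2")
  expect_equal(classify_response(15, +1, "crossed", cfg)$class, "P1")
  expect_equal(classify_response(47, +1, "homonymous", cfg)$class, "P3")
  expect_equal(classify_response(18, -1, "diagonal", cfg)$class, "N1")
  # onsets below 7 ms are artifacts
  expect_null(classify_response(5, +1, "homonymous", cfg))
  expect_null(classify_response(65, +1, "homonymous", cfg))
  # gaps between printed windows: nearer window, flagged
  g1 <- classify_response(18.4, +1, "homonymous", cfg)
  expect_equal(g1$class, "P1")
  expect_true(g1$gap_flagged)
  g2 <- classify_response(34.7, +1, "homonymous", cfg)
  expect_equal(g2$class, "P3")
  expect_true(g2$gap_flagged)
})

test_that("net reflex value implements (stim - blEMG) / blEMG with scale invariance", {
  t_ms <- seq(0, 20, by = 0.5)
  base <- rep(1, length(t_ms))
  stim <- rep(2, length(t_ms))
  expect_equal(net_reflex_value(stim, base, t_ms, c(5, 15)), 1)
  expect_equal(net_reflex_value(base, base, t_ms, c(5, 15)), 0)
  expect_equal(net_reflex_value(0.5 * base, base, t_ms, c(5, 15)), -0.5)
  # doubling every trace leaves the value unchanged, exactly
  set.seed(1)
  stim2 <- 1 + runif(length(t_ms))
  base2 <- 0.5 + runif(length(t_ms))
  v1 <- net_reflex_value(stim2, base2, t_ms, c(5, 15))
  v2 <- net_reflex_value(2 * stim2, 2 * base2, t_ms, c(5, 15))
  expect_identical(v1, v2)
  # division guard
  expect_warning(v0 <- net_reflex_value(stim, 0 * base, t_ms, c(5, 15)), "floor")
  expect_true(is.na(v0))
})

test_that("a noise-free injected bump is detected within 2 ms of its onset", {
  cfg <- session_config("tied_slow", n_cycles = 60, seed = 2, noiseless = TRUE)
  gt <- default_ground_truth(cfg)
  gt$responses <- tibble::tibble(muscle = "TA", class = "P1", onset_ms = 12,
                                 duration_ms = 8, profile = list(rep(0.5, 10)))
  s <- simulate_session(cfg, gt)
  rr <- reflex_responses(s, analysis_config(min_stim_per_bin = 1), muscles = "TA")
  hit <- dplyr::filter(rr, status == "response")
  expect_gt(nrow(hit), 5)
  expect_true(all(abs(hit$onset_ms - 12) <= 2))
  expect_true(all(hit$latency_class == "P1"))
})

test_that("noise-free recovery returns the injected profile exactly", {
  s <- noiseless_session()
  gtr <- s$ground_truth$responses
  row <- which(gtr$muscle == "SOL" & gtr$class == "N1")
  win <- c(gtr$onset_ms[row], gtr$onset_ms[row] + gtr$duration_ms[row])
  prof <- net_reflex_profile(s, "SOL", window_ms = win) |>
    dplyr::filter(n_stim > 0)
  expect_gte(nrow(prof), 8)
  injected <- gtr$profile[[row]][prof$bin + 1]
  expect_equal(prof$net_value, injected, tolerance = 1e-9)
  expect_gt(stats::cor(prof$net_value, injected), 1 - 1e-9)
})

test_that("normalization scales to the signed per-muscle maximum", {
  d <- tibble::tibble(muscle = "M", relation = "homonymous", latency_window = 1L,
                      net_value = c(90, -30, 45))
  out <- normalize_responses(d)
  expect_equal(out$normalized_value, c(100, -100 / 3, 50))
  # all equal positive values all map to 100%
  d2 <- dplyr::mutate(d, net_value = 2)
  expect_equal(normalize_responses(d2)$normalized_value, rep(100, 3))
  # all-zero maps to zero
  d3 <- dplyr::mutate(d, net_value = 0)
  expect_equal(normalize_responses(d3)$normalized_value, rep(0, 3))
  # abs variant uses the maximal magnitude
  d4 <- tibble::tibble(muscle = "M", relation = "homonymous", latency_window = 1L,
                       net_value = c(50, -100))
  expect_equal(normalize_responses(d4, method = "abs")$normalized_value, c(50, -100))
})

test_that("modulation index is max minus min and can exceed 100% with sign changes", {
  d <- tibble::tibble(muscle = "M", relation = "homonymous", latency_window = 1L,
                      condition = "tied_slow", bin = 0:9,
                      normalized_value = c(100, 60, 20, -20, -10, 0, 10, 30, 50, 80))
  idx <- modulation_index(d)
  expect_equal(idx$index, 120)
  d2 <- dplyr::mutate(d, normalized_value = 40)
  expect_equal(modulation_index(d2)$index, 0)
  d3 <- d[1:2, ]
  d3$normalized_value <- c(100, 40)
  expect_equal(modulation_index(d3)$index, 60)
  # a single bin is not enough
  expect_true(is.na(modulation_index(d[1, ])$index))
})

test_that("bins with too few stimuli are reported, not silently dropped", {
  s <- noiseless_session()
  rr <- reflex_responses(s, analysis_config(min_stim_per_bin = 100), muscles = "SOL")
  expect_equal(nrow(rr), 10)
  expect_true(all(rr$status == "insufficient"))
})
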
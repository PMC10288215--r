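# Cycle/stance/swing durations, stride and step lengths.

test_that("cycles follow from consecutive contacts with stance and swing splitting the cycle", {
  ev <- simple_limb_events(contacts = c(0, 1, 2), liftoffs = c(0.6, 1.6))
  cyc <- gait_cycles(ev, c(LH = 0.4))
  expect_equal(nrow(cyc), 2)
  expect_equal(cyc$cycle_duration, c(1, 1))
  expect_equal(cyc$stance_duration, c(0.6, 0.6))
  expect_equal(cyc$swing_duration, c(0.4, 0.4))
})

test_that("a single contact opens no cycle and swapped events are rejected", {
  one <- simple_limb_events(contacts = 0.5, liftoffs = numeric(0))
  expect_equal(nrow(gait_cycles(one, c(LH = 0.4))), 0)

  swapped <- tibble::tibble(
    limb = "LH", event = c("liftoff", "contact", "liftoff", "contact"),
    time_s = c(0.2, 0.5, 0.4, 1.0), x_m = 0
  )
  expect_error(gait_cycles(swapped, c(LH = 0.4)), "increasing|alternate")

  nonalt <- tibble::tibble(
    limb = "LH", event = c("contact", "contact", "liftoff"),
    time_s = c(0, 0.5, 0.8), x_m = 0
  )
  expect_error(gait_cycles(nonalt, c(LH = 0.4)), "alternate")
})

test_that("stride length is paw travel plus belt travel during swing", {
  # |dx| = 0.20 m, belt 0.4 m/s, swing 0.30 s -> 0.32 m
  ev <- simple_limb_events(contacts = c(0, 1), liftoffs = 0.7,
                           contact_x = c(0.1, 0.1), liftoff_x = -0.1)
  cyc <- gait_cycles(ev, c(LH = 0.4))
  expect_equal(cyc$stride_length, 0.2 + 0.4 * 0.3)

  # belt 0.8 m/s, |dx| = 0.25, swing 0.25 -> 0.45 m
  ev2 <- simple_limb_events(contacts = c(0, 1), liftoffs = 0.75,
                            contact_x = c(0.12, 0.12), liftoff_x = -0.13)
  expect_equal(gait_cycles(ev2, c(LH = 0.8))$stride_length, 0.45)

  # zero swing: stride is just the paw travel
  ev3 <- simple_limb_events(contacts = c(0, 1), liftoffs = 1 - 1e-9,
                            contact_x = c(0.1, 0.1), liftoff_x = -0.1)
  expect_equal(gait_cycles(ev3, c(LH = 0.4))$stride_length, 0.2, tolerance = 1e-6)

  # missing position: NA with a warning
  ev4 <- simple_limb_events(contacts = c(0, 1), liftoffs = 0.6,
                            contact_x = c(NA, 0.1), liftoff_x = -0.1)
  expect_warning(cyc4 <- gait_cycles(ev4, c(LH = 0.4)), "missing position")
  expect_true(is.na(cyc4$stride_length))
})

test_that("step length is the paw separation at the leading limb's contact", {
  # trailing paw at x = 0.10 m when the leading limb contacts at 0.25 m
  ev <- dplyr::bind_rows(
    simple_limb_events("LH", contacts = c(0, 1), liftoffs = 0.6,
                       contact_x = c(0.3, 0.3), liftoff_x = 0.06),
    # trailing limb LH is in stance at t = 0.5: x = 0.3 - 0.4*0.5 = 0.10
    simple_limb_events("RH", contacts = 0.5, liftoffs = numeric(0),
                       contact_x = 0.25, liftoff_x = numeric(0))
  )
  sl <- step_length(ev, leading = "RH", trailing = "LH",
                    belt_speeds = c(left = 0.4, right = 0.4))
  expect_equal(sl$trailing_x, 0.10)
  expect_equal(sl$step_length, 0.15)

  # both paws at the same x: step length 0
  ev2 <- dplyr::bind_rows(
    simple_limb_events("LH", contacts = c(0, 1), liftoffs = 0.6,
                       contact_x = c(0.3, 0.3), liftoff_x = 0.06),
    simple_limb_events("RH", contacts = 0.5, liftoffs = numeric(0),
                       contact_x = 0.10, liftoff_x = numeric(0))
  )
  expect_equal(step_length(ev2, "RH", "LH", c(left = 0.4, right = 0.4))$step_length, 0)

  # instant outside the trailing limb's span: NA
  ev3 <- dplyr::bind_rows(
    simple_limb_events("LH", contacts = c(1, 2), liftoffs = 1.6),
    simple_limb_events("RH", contacts = 0.5, liftoffs = numeric(0),
                       contact_x = 0.25, liftoff_x = numeric(0))
  )
  expect_true(is.na(step_length(ev3, "RH", "LH", c(left = 0.4, right = 0.4))$step_length))
})

test_that("stance plus swing equals the cycle exactly on generated sessions", {
  s <- noisy_session()
  kin <- gait_cycles(s$events, session_belt_speeds_of(s$config), s$stims$time_s)
  expect_identical(kin$stance_duration + kin$swing_duration, kin$cycle_duration)
  expect_true(all(kin$cycle_duration > 0 & kin$stance_duration > 0 & kin$swing_duration > 0))
})

test_that("on noise-free tied-belt gait the stride equals belt speed times cycle duration", {
  s <- noiseless_session()
  kin <- gait_cycles(s$events, session_belt_speeds_of(s$config))
  expect_equal(kin$stride_length, kin$belt_speed * kin$cycle_duration,
               tolerance = 1e-9)
})

test_that("dropping stimulated cycles leaves the remaining cycles untouched", {
  s <- noisy_session()
  kin <- gait_cycles(s$events, session_belt_speeds_of(s$config), s$stims$time_s)
  expect_gt(sum(kin$has_stimulation), 0)
  unstim <- dplyr::filter(kin, !has_stimulation)
  again <- gait_cycles(s$events, session_belt_speeds_of(s$config), s$stims$time_s) |>
    dplyr::filter(!has_stimulation)
  expect_identical(unstim, again)
  # summary of unstimulated cycles is unaffected by the presence of stimulated rows
  expect_equal(mean(unstim$cycle_duration),
               mean(kin$cycle_duration[!kin$has_stimulation]))
})
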
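# Circular mean/resultant length, Rayleigh and Watson-Williams tests,
# von Mises sampling, symmetry indexes.

test_that("circular mean and resultant length handle the canonical cases", {
  cs <- circ_mean_r(rep(37, 10))
  expect_equal(cs$r, 1)
  expect_equal(cs$mean_deg, 37)

  expect_warning(cs4 <- circ_mean_r(c(0, 90, 180, 270)), "undefined")
  expect_equal(cs4$r, 0, tolerance = 1e-12)
  expect_true(is.na(cs4$mean_deg))

  expect_warning(cs2 <- circ_mean_r(c(0, 180)), "undefined")
  expect_equal(cs2$r, 0, tolerance = 1e-12)

  # wrap-around: mean of 350 and 10 is 0, not 180
  expect_equal(circ_mean_r(c(350, 10))$mean_deg, 0, tolerance = 1e-9)
})

test_that("r is rotation invariant and the mean direction shifts with rotation", {
  set.seed(101)
  for (i in 1:20) {
    a <- runif(15, 0, 360)
    delta <- runif(1, 0, 360)
    base <- circ_mean_r(a)
    rot <- circ_mean_r((a + delta) %% 360)
    expect_equal(rot$r, base$r, tolerance = 1e-12)
    diff <- (rot$mean_deg - base$mean_deg - delta) %% 360
    expect_true(min(diff, 360 - diff) < 1e-9)
  }
})

test_that("Rayleigh statistic is n*r^2 and matches an independent reference", {
  # z = n * r^2 with r = 1
  rt <- rayleigh_test(rep(37, 10))
  expect_equal(rt$statistic, 10)

  # uniform four-point sample: r = 0, z = 0, p = 1 to approximation order
  suppressWarnings(rt0 <- rayleigh_test(c(0, 90, 180, 270)))
  expect_equal(rt0$statistic, 0, tolerance = 1e-12)
  expect_equal(rt0$p.value, 1, tolerance = 1e-6)

  # frozen values from an independent circular-statistics implementation
  # (pingouin.circ_rayleigh) on fixed samples
  a <- c(10, 40, 65, 80, 120, 135, 150, 200, 210, 250, 300, 330, 345,
         20, 55, 95, 170, 190, 280, 310)
  rta <- rayleigh_test(a)
  expect_equal(rta$statistic, 0.185261897691, tolerance = 1e-6)
  expect_equal(rta$p.value, 0.834315648471, tolerance = 1e-6)

  b <- c(350, 355, 2, 8, 12, 15, 345, 5)
  rtb <- rayleigh_test(b)
  expect_equal(rtb$statistic, 7.761031665616, tolerance = 1e-6)
  expect_equal(rtb$p.value, 2.43129588772e-05, tolerance = 1e-6)

  rtc <- rayleigh_test(rep(37, 10))
  expect_equal(rtc$p.value, 4.57780620299e-07, tolerance = 1e-6)
})

test_that("Rayleigh p decreases monotonically in r at fixed n", {
  set.seed(202)
  samples <- lapply(c(0.5, 2, 8, 32), function(k) rvonmises(12, 90, k))
  rs <- vapply(samples, function(a) circ_mean_r(a)$r, numeric(1))
  ps <- vapply(samples, function(a) rayleigh_test(a)$p.value, numeric(1))
  ord <- order(rs)
  expect_true(all(diff(ps[ord]) <= 0))
})

test_that("von Mises draws recover the configured mean and concentration", {
  expect_equal(rvonmises(5, 123, Inf), rep(123, 5))
  set.seed(303)
  a <- rvonmises(1000, 135, 8)
  cs <- circ_mean_r(a)
  dd <- abs(cs$mean_deg - 135)
  expect_lt(min(dd, 360 - dd), 2)
  r_expected <- besselI(8, 1) / besselI(8, 0)
  expect_lt(abs(cs$r - r_expected), 0.05)
  # uniform limit
  set.seed(304)
  u <- rvonmises(2000, 0, 0)
  expect_lt(circ_mean_r(u)$r, 0.07)
})

test_that("Watson-Williams separates distinct mean directions and rejects degenerate input", {
  set.seed(404)
  a <- c(rvonmises(20, 0, 20), rvonmises(20, 180, 20))
  g <- rep(c("a", "b"), each = 20)
  ww <- watson_williams(a, g)
  expect_lt(ww$p.value, 0.001)
  expect_equal(ww$df1, 1)
  expect_equal(ww$df2, 38)

  # identical samples within every group: degenerate denominator
  expect_error(watson_williams(rep(c(10, 200), each = 5), rep(c("a", "b"), each = 5)),
               "Degenerate")

  # same distribution: typically not significant
  set.seed(405)
  a2 <- c(rvonmises(25, 90, 10), rvonmises(25, 90, 10))
  ww2 <- watson_williams(a2, rep(c("a", "b"), each = 25))
  expect_gt(ww2$p.value, 0.01)
})

test_that("Watson-Williams F matches an independently coded textbook formula", {
  set.seed(406)
  angles <- c(rvonmises(20, 40, 6), rvonmises(20, 70, 6))
  group <- rep(c("g1", "g2"), each = 20)
  ww <- watson_williams(angles, group)

  # direct transcription of the high-concentration F with the 3/(8k) correction
  rad <- angles * pi / 180
  Ri <- vapply(split(rad, group), function(g) {
    sqrt(sum(cos(g))^2 + sum(sin(g))^2)
  }, numeric(1))
  R <- sqrt(sum(cos(rad))^2 + sum(sin(rad))^2)
  N <- length(rad); k <- 2
  rw <- sum(Ri) / N
  kap <- if (rw < 0.53) 2 * rw + rw^3 + 5 * rw^5 / 6 else if (rw < 0.85)
    -0.4 + 1.39 * rw + 0.43 / (1 - rw) else 1 / (rw^3 - 4 * rw^2 + 3 * rw)
  Fref <- (1 + 3 / (8 * kap)) * ((N - k) * (sum(Ri) - R)) / ((k - 1) * (N - sum(Ri)))
  pref <- pf(Fref, k - 1, N - k, lower.tail = FALSE)
  expect_equal(ww$statistic, Fref, tolerance = 1e-10)
  expect_equal(ww$p.value, pref, tolerance = 1e-10)
})

test_that("symmetry index maps alternation to 0% and is mirror symmetric about 180", {
  expect_equal(symmetry_index(180), 0)
  expect_equal(symmetry_index(90), 50)
  expect_equal(symmetry_index(360), 100)
  expect_equal(symmetry_index(0), 100)
  th <- seq(0, 359.5, by = 7.3)
  expect_equal(symmetry_index(th), symmetry_index(360 - th))
})

test_that("tidy methods return one-row summaries", {
  rt <- rayleigh_test(c(1, 5, 9, 12, 350, 355))
  expect_s3_class(tidy(rt), "tbl_df")
  expect_named(tidy(rt), c("statistic", "p.value", "r", "mean_deg", "n"))
})
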
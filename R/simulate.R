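# Synthetic four-limb locomotor sessions with stimulus trains and injected
# phase-modulated reflex responses, plus the ground truth needed to test
# every downstream stage.

snap_to_grid <- function(t, rate) round(t * rate) / rate

clamp <- function(x, lo = -3, hi = 3) pmin(pmax(x, lo), hi)

session_belt_speeds <- function(config) {
  c(LF = config$left_speed, LH = config$left_speed,
    RF = config$right_speed, RH = config$right_speed)
}

coupling_target <- function(config, coupling, kind) {
  ct <- config$coupling_targets
  row <- ct[ct$coupling == coupling & ct$kind == kind, ]
  if (nrow(row) != 1) {
    abort(sprintf("No unique %s/%s coupling target in config.", coupling, kind))
  }
  row
}

muscle_window <- function(config, muscle_row) {
  if (!is.na(muscle_row$window_start) && !is.na(muscle_row$window_end)) {
    return(c(muscle_row$window_start, muscle_row$window_end))
  }
  f <- speed_stance_fraction(config, belt_speed_of(config, muscle_row$limb))
  if (muscle_row$role == "extensor") c(0, f) else c(min(f + 0.05, 0.85), 0.95)
}

# Signed 10-bin amplitude profile shaped as a raised cosine over the
# muscle's activity window (`where = "active"`) or its complement, with
# circular wrap-around of the window.
phase_profile <- function(window, amp, where = c("active", "inactive"),
                          n_bins = 10L) {
  where <- match.arg(where)
  len <- window[2] - window[1]
  start <- window[1] %% 1
  if (where == "inactive") {
    start <- window[2] %% 1
    len <- 1 - len
  }
  if (len <= 0) return(rep(0, n_bins))
  if (len >= 1) return(rep(amp, n_bins))
  centers <- (seq_len(n_bins) - 0.5) / n_bins
  d <- (centers - start) %% 1
  w <- ifelse(d <= len, 0.5 * (1 - cos(2 * pi * d / len)), 0)
  amp * w
}

#' Default ground-truth reflex responses for a synthetic session
#'
#' One or two injected responses per muscle with latencies at the centres of
#' the short (P1/N1), mid (P2/N2) and long (P3/N3) windows and signed 10-bin
#' amplitude profiles tied to each muscle's activity window: extensors
#' receive short-latency inhibition during activity (and, for SOL, a
#' long-latency excitation while inactive), flexors short/mid-latency
#' excitation during their burst. Amplitudes are expressed in net-reflex
#' units (fractional change of the baseline EMG integrated over the response
#' window).
#'
#' @param config A [session_config()].
#' @return Object of class `"reflex_ground_truth"`: list with `responses`
#'   (tibble: `muscle`, `class`, `onset_ms`, `duration_ms`, `profile`
#'   list-column of 10 signed values), `activity_windows`,
#'   `coupling_targets`, `stance_fractions`.
#' @export
default_ground_truth <- function(config) {
  rows <- purrr::map_dfr(seq_len(nrow(config$muscles)), function(i) {
    m <- config$muscles[i, ]
    w <- muscle_window(config, m)
    spec <- switch(m$muscle,
      SOL = list(list(class = "N1", onset = 12, dur = 10,
                      profile = phase_profile(w, -0.4, "active")),
                 list(class = "P3", onset = 47, dur = 12,
                      profile = phase_profile(w, 0.5, "inactive"))),
      TA  = list(list(class = "P1", onset = 12, dur = 8,
                      profile = phase_profile(w, 0.8, "active"))),
      SRT = list(list(class = "P2", onset = 26, dur = 10,
                      profile = phase_profile(w, 0.5, "active"))),
      list(list(class = "P2", onset = 26, dur = 10,
                profile = phase_profile(w, 0.4, "active")))
    )
    purrr::map_dfr(spec, function(s) {
      tibble::tibble(muscle = m$muscle, class = s$class,
                     onset_ms = s$onset, duration_ms = s$dur,
                     profile = list(s$profile))
    })
  })
  check_ground_truth(rows)
  aw <- purrr::map_dfr(seq_len(nrow(config$muscles)), function(i) {
    m <- config$muscles[i, ]
    w <- muscle_window(config, m)
    tibble::tibble(muscle = m$muscle, limb = m$limb,
                   start_frac = w[1], end_frac = w[2])
  })
  structure(
    list(responses = rows,
         activity_windows = aw,
         coupling_targets = config$coupling_targets,
         stance_fractions = c(left = speed_stance_fraction(config, config$left_speed),
                              right = speed_stance_fraction(config, config$right_speed)),
         truncated_stims = 0L),
    class = "reflex_ground_truth"
  )
}

check_ground_truth <- function(responses) {
  wins <- list(`1` = c(7, 18), `2` = c(19, 34), `3` = c(35, 60))
  for (i in seq_len(nrow(responses))) {
    cls <- responses$class[i]
    k <- substr(cls, 2, 2)
    w <- wins[[k]]
    if (is.null(w) || responses$onset_ms[i] < w[1] || responses$onset_ms[i] > w[2]) {
      abort(sprintf("Ground-truth onset %.1f ms is outside the %s window.",
                    responses$onset_ms[i], cls))
    }
    if (length(responses$profile[[i]]) != 10) {
      abort("Ground-truth amplitude profiles must have 10 phase values.")
    }
  }
  invisible(responses)
}

#' Generate four-limb gait events
#'
#' Builds contact/liftoff sequences for the four limbs. The left forelimb is
#' the base chain with cycle durations drawn around the speed-dependent mean;
#' the right forelimb, left hindlimb and right hindlimb contacts are placed
#' from von Mises draws around the configured phase-coupling targets
#' (forelimb and hindlimb pairs, homolateral pair; the diagonal coupling
#' follows). Paw contact positions realize the configured gap-interval
#' targets: the non-reference homologous paw lands a step length of
#' `gap/360 x reference stride` away from the reference paw. During stance
#' the paw rides the belt backward; all event times are snapped to the EMG
#' sample grid.
#'
#' @param config A [session_config()].
#' @param seed Seed applied before drawing (default `config$seed`); pass
#'   `NULL` to draw from the current RNG stream.
#' @return Gait event tibble (`limb`, `event`, `time_s`, `x_m`).
#' @export
simulate_gait_events <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  rate <- cfg$emg_sample_rate
  n <- cfg$n_cycles
  n_gen <- n + 3L
  v_eff <- mean(c(cfg$left_speed, cfg$right_speed))
  dbar <- speed_cycle_duration(cfg, v_eff)

  durs <- dbar * (1 + cfg$duration_cv * clamp(rnorm(n_gen)))
  lf_ct <- snap_to_grid(0.3 + c(0, cumsum(durs)), rate)

  place_by_phase <- function(ref_contacts, target_deg, kappa) {
    m <- length(ref_contacts) - 1
    theta <- rvonmises(m, target_deg, kappa)
    snap_to_grid(ref_contacts[-length(ref_contacts)] +
                   theta / 360 * diff(ref_contacts), rate)
  }
  tf <- coupling_target(cfg, "forelimb", "phase")
  th <- coupling_target(cfg, "hindlimb", "phase")
  tl <- coupling_target(cfg, "homolateral", "phase")
  rf_ct <- place_by_phase(lf_ct, tf$target_deg, tf$kappa)
  lh_ct <- place_by_phase(lf_ct, tl$target_deg, tl$kappa)
  rh_ct <- place_by_phase(lh_ct, th$target_deg, th$kappa)

  contacts <- list(LF = lf_ct, RF = rf_ct, LH = lh_ct, RH = rh_ct)
  speeds <- session_belt_speeds(cfg)

  liftoffs_of <- function(ct, v) {
    f <- speed_stance_fraction(cfg, v)
    snap_to_grid(ct[-length(ct)] + f * diff(ct), rate)
  }
  liftoffs <- purrr::imap(contacts, ~ liftoffs_of(.x, speeds[.y]))

  base_x <- c(LF = 0.15, LH = -0.15)
  xjit <- function(k) cfg$contact_x_sd * rnorm(k)
  limb_tbl <- function(limb, ct, lo, ct_x) {
    lo_x <- ct_x[seq_along(lo)] - speeds[limb] * (lo - ct[seq_along(lo)])
    tibble::tibble(
      limb = limb,
      event = c(rep("contact", length(ct)), rep("liftoff", length(lo))),
      time_s = c(ct, lo),
      x_m = c(ct_x, lo_x)
    )
  }

  ev <- list()
  for (ref in c("LF", "LH")) {
    ct <- contacts[[ref]]
    ev[[ref]] <- limb_tbl(ref, ct, liftoffs[[ref]], base_x[ref] + xjit(length(ct)))
  }
  # homologous limbs: contact placement from gap-interval draws
  for (pair in list(c("RF", "LF", "forelimb"), c("RH", "LH", "hindlimb"))) {
    limb <- pair[1]; ref <- pair[2]
    tg <- coupling_target(cfg, pair[3], "gap")
    ct <- contacts[[limb]]
    gamma <- rvonmises(length(ct), tg$target_deg, tg$kappa)
    ref_ct <- contacts[[ref]]
    i <- findInterval(ct, ref_ct)
    ok <- i >= 1 & i < length(ref_ct)
    stride_ref <- speeds[ref] * (ref_ct[pmin(i + 1, length(ref_ct))] - ref_ct[pmax(i, 1)])
    x_ref <- limb_position(ev[[ref]], ref, speeds[ref], ct)
    ct_x <- x_ref + gamma / 360 * stride_ref
    ct_x[!ok | is.na(ct_x)] <- base_x[ref]
    ev[[limb]] <- limb_tbl(limb, ct, liftoffs[[limb]], ct_x)
  }

  # trim every limb to n full cycles over a common span
  events <- purrr::map_dfr(names(ev), function(lb) {
    e <- ev[[lb]]
    ct_times <- sort(e$time_s[e$event == "contact"])
    keep_ct <- ct_times[2:min(length(ct_times), n + 2L)]
    e[(e$event == "contact" & e$time_s %in% keep_ct) |
        (e$event == "liftoff" & e$time_s > keep_ct[1] & e$time_s < keep_ct[length(keep_ct)]), ]
  })
  events <- events[order(events$limb, events$time_s), ]
  validate_events(events)
  events
}

#' Generate cutaneous stimulation times
#'
#' Stimuli are delivered every 2-4 locomotor cycles of the reference limb
#' (uniform over the configured gap range) at a delay uniform within the
#' cycle, so that all 10 phase bins are populated. Times are snapped to the
#' EMG sample grid.
#'
#' @inheritParams simulate_gait_events
#' @param events Gait event table from [simulate_gait_events()].
#' @return Tibble `time_s`, `nerve`, `limb`.
#' @export
simulate_stim_times <- function(config, events, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  rate <- cfg$emg_sample_rate
  ct <- limb_events(events, cfg$reference_limb)
  ct <- ct$time_s[ct$event == "contact"]
  m <- length(ct) - 1
  if (m < 20) abort("Stimulus generation needs at least 20 reference cycles.")
  gaps <- seq(cfg$stim$cycle_gap_range[1], cfg$stim$cycle_gap_range[2])
  times <- numeric(0)
  i <- 1L + sample(gaps, 1)
  while (i <= m - 1L) {
    u <- runif(1)
    t <- floor((ct[i] + u * (ct[i + 1] - ct[i])) * rate) / rate
    t <- min(max(t, ct[i]), ct[i + 1] - 1 / rate)
    times <- c(times, t)
    i <- i + sample(gaps, 1)
  }
  tibble::tibble(time_s = times, nerve = cfg$stim_nerve, limb = cfg$stim_limb)
}

envelope_from_contacts <- function(n_samples, rate, contacts, window,
                                   base = 0.05, amp = 1) {
  t <- (seq_len(n_samples) - 1) / rate
  i <- findInterval(t, contacts)
  frac <- rep(NA_real_, n_samples)
  ok <- i >= 1 & i < length(contacts)
  frac[ok] <- (t[ok] - contacts[i[ok]]) / (contacts[i[ok] + 1] - contacts[i[ok]])
  a <- window[1]; b <- window[2]
  env <- rep(base, n_samples)
  inb <- !is.na(frac) & frac >= a & frac <= b
  env[inb] <- base + amp * 0.5 * (1 - cos(2 * pi * (frac[inb] - a) / (b - a)))
  env
}

trapz_sum <- function(y) sum(y[-1] + y[-length(y)]) / 2

#' Generate multi-channel EMG with injected reflex responses
#'
#' Each channel is a non-negative burst envelope (raised-cosine burst over the
#' muscle's activity window in each cycle of its limb) with multiplicative and
#' additive Gaussian noise. For every stimulus, a smooth raised-cosine bump is
#' added at the ground-truth latency; its discrete integral equals the
#' profile value of the stimulus phase bin times the integral of the clean
#' envelope over the bump support, so injected amplitudes are in net-reflex
#' units. Negative (inhibitory) bumps never drive the signal below zero
#' (final clamp at 0).
#'
#' @inheritParams simulate_stim_times
#' @param stims Stimulation table from [simulate_stim_times()].
#' @param ground_truth A `"reflex_ground_truth"` (see
#'   [default_ground_truth()]).
#' @return List with `signal` (samples x channels matrix), `rate_hz`,
#'   `channels` (tibble `channel`, `muscle`, `limb`) and `truncated_stims`
#'   (count of bumps clipped at the recording edge).
#' @export
simulate_emg <- function(config, events, stims, ground_truth = default_ground_truth(config),
                         seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  rate <- cfg$emg_sample_rate
  t_end <- max(events$time_s) + 0.3
  n_samples <- floor(t_end * rate) + 1L

  ref_ev <- limb_events(events, cfg$reference_limb)
  ref_ct <- ref_ev$time_s[ref_ev$event == "contact"]
  stim_bins <- assign_stim_phase(stims$time_s, ref_ct, n_bins = 10L,
                                 allow_outside = TRUE)

  signal <- matrix(0, nrow = n_samples, ncol = nrow(cfg$muscles))
  truncated <- 0L
  for (ch in seq_len(nrow(cfg$muscles))) {
    m <- cfg$muscles[ch, ]
    ct <- limb_events(events, m$limb)
    ct <- ct$time_s[ct$event == "contact"]
    w <- muscle_window(cfg, m)
    env <- envelope_from_contacts(n_samples, rate, ct, w)
    sig <- env * (1 + cfg$noise$mult * rnorm(n_samples)) +
      cfg$noise$add * rnorm(n_samples)
    gt <- ground_truth$responses[ground_truth$responses$muscle == m$muscle, ]
    if (nrow(gt) && nrow(stims)) {
      for (s in seq_len(nrow(stims))) {
        bin <- stim_bins[s]
        if (is.na(bin)) next
        for (g in seq_len(nrow(gt))) {
          ampl <- gt$profile[[g]][bin + 1]
          if (ampl == 0) next
          i0 <- round((stims$time_s[s] + gt$onset_ms[g] / 1000) * rate) + 1L
          len <- max(4L, round(gt$duration_ms[g] / 1000 * rate))
          idx <- i0:(i0 + len)
          if (i0 < 1) next
          if (max(idx) > n_samples) {
            truncated <- truncated + 1L
            idx <- idx[idx <= n_samples]
            if (length(idx) < 2) next
          }
          u <- seq(0, 1, length.out = length(idx))
          K <- 0.5 * (1 - cos(2 * pi * u))
          I_K <- trapz_sum(K)
          I_env <- trapz_sum(env[idx])
          sig[idx] <- sig[idx] + (ampl * I_env / I_K) * K
        }
      }
    }
    signal[, ch] <- pmax(sig, 0)
  }
  list(signal = signal, rate_hz = rate,
       channels = tibble::tibble(channel = seq_len(nrow(cfg$muscles)),
                                 muscle = cfg$muscles$muscle,
                                 limb = cfg$muscles$limb),
       truncated_stims = truncated)
}

#' Simulate a complete locomotor session
#'
#' Seeds one RNG stream from `config$seed` and draws gait events, stimulus
#' times and EMG from it in order, so that identical configurations give
#' bit-identical sessions.
#'
#' @param config A [session_config()].
#' @param ground_truth Injected reflex responses; default
#'   [default_ground_truth()].
#' @return Object of class `"gait_session"`: list with `events`, `stims`,
#'   `emg` (`signal`, `rate_hz`, `channels`), `ground_truth`, `config`.
#' @export
#' @examples
#' cfg <- session_config("tied_slow", n_cycles = 30, seed = 7)
#' s <- simulate_session(cfg)
#' s
simulate_session <- function(config, ground_truth = default_ground_truth(config)) {
  set.seed(config$seed)
  events <- simulate_gait_events(config, seed = NULL)
  stims <- simulate_stim_times(config, events, seed = NULL)
  emg <- simulate_emg(config, events, stims, ground_truth, seed = NULL)
  ground_truth$truncated_stims <- emg$truncated_stims
  structure(
    list(events = events, stims = stims,
         emg = emg[c("signal", "rate_hz", "channels")],
         ground_truth = ground_truth, config = config),
    class = "gait_session"
  )
}

#' @export
print.gait_session <- function(x, ...) {
  cat(sprintf("<gait_session> %s: %d gait events, %d stimuli, %d EMG channels @ %g Hz\n",
              x$config$condition, nrow(x$events), nrow(x$stims),
              ncol(x$emg$signal), x$emg$rate_hz))
  invisible(x)
}
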
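# Configuration objects for the synthetic session generator and the analysis.

CONDITIONS <- c("tied_slow", "tied_fast", "split_slow", "split_fast")

condition_speeds <- function(condition, slow = 0.4, fast = 0.8) {
  switch(condition,
    tied_slow  = c(left = slow, right = slow),
    tied_fast  = c(left = fast, right = fast),
    split_slow = c(left = slow, right = fast),
    split_fast = c(left = fast, right = slow),
    abort(sprintf("Unknown condition '%s'.", condition))
  )
}

#' Default muscle set for synthetic sessions
#'
#' A compact bilateral-style set covering the stimulated hindlimb and one
#' forelimb: anterior sartorius (SRT, hip flexor, the cycle-reference muscle),
#' soleus (SOL, ankle extensor), tibialis anterior (TA, ankle flexor) and
#' extensor carpi ulnaris (ECU, wrist extensor). Extensors burst during
#' stance, flexors during swing; the exact activity window is derived from
#' the limb's stance fraction at generation time unless `window_start`/
#' `window_end` (fractions of the cycle) are given.
#'
#' @return Tibble with columns `muscle`, `limb`, `role`, `window_start`,
#'   `window_end`.
#' @export
default_muscles <- function() {
  tibble::tibble(
    muscle = c("SRT", "SOL", "TA", "ECU"),
    limb   = c("LH", "LH", "LH", "LF"),
    role   = c("flexor", "extensor", "flexor", "extensor"),
    window_start = NA_real_,
    window_end   = NA_real_
  )
}

#' Default interlimb coupling targets per condition
#'
#' Mean phase intervals (contact timing) and gap intervals (contact placement)
#' with von Mises concentrations, per limb coupling. Homologous pairs
#' alternate at 180 degrees; the homolateral pair leads at 270 degrees (the
#' diagonal coupling at 90 degrees follows from these two). Gap intervals sit
#' at 180 degrees under tied belts and move to 270/90 degrees under split
#' belts. Concentrations are tightest for tied-fast and loosest (especially
#' spatially) for split conditions.
#'
#' @param condition One of `"tied_slow"`, `"tied_fast"`, `"split_slow"`,
#'   `"split_fast"`.
#' @return Tibble with columns `coupling`, `kind`, `reference`, `other`,
#'   `target_deg`, `kappa`.
#' @export
default_coupling_targets <- function(condition = "tied_slow") {
  condition <- match.arg(condition, CONDITIONS)
  kappa_phase <- switch(condition, tied_slow = 30, tied_fast = 60, 20)
  kappa_gap   <- switch(condition, tied_slow = 5, tied_fast = 20, 4)
  gap_target  <- switch(condition, split_slow = 270, split_fast = 90, 180)
  tibble::tibble(
    coupling   = c("forelimb", "hindlimb", "homolateral", "forelimb", "hindlimb"),
    kind       = c("phase", "phase", "phase", "gap", "gap"),
    reference  = c("LF", "LH", "LF", "LF", "LH"),
    other      = c("RF", "RH", "LH", "RF", "RH"),
    target_deg = c(180, 180, 270, gap_target, gap_target),
    kappa      = c(kappa_phase, kappa_phase, kappa_phase, kappa_gap, kappa_gap)
  )
}

#' Configuration of a synthetic locomotor session
#'
#' Bundles every parameter of the four-limb synthetic session generator:
#' locomotor condition and belt speeds, number of cycles, the linear
#' speed-to-cycle-duration and speed-to-stance-fraction models, interlimb
#' coupling targets, muscle set, EMG sample rate and noise levels, and the
#' cutaneous stimulation train specification.
#'
#' @param condition Locomotor condition; sets default belt speeds (0.4 m/s
#'   slow, 0.8 m/s fast) and coupling targets.
#' @param left_speed,right_speed Belt speeds in m/s; default from `condition`.
#' @param n_cycles Number of locomotor cycles to generate (>= 20). The
#'   default 360 yields roughly 120 stimuli, one every 2-4 cycles.
#' @param emg_sample_rate EMG sampling rate in Hz (>= 1000; reflex response
#'   windows span 7-60 ms).
#' @param muscles Muscle table as in [default_muscles()].
#' @param coupling_targets Coupling target table as in
#'   [default_coupling_targets()].
#' @param cycle_model,stance_model Linear maps `intercept + slope * speed`
#'   giving mean cycle duration (s, from the mean of the two belt speeds) and
#'   stance fraction (from the limb's own belt speed).
#' @param duration_cv Coefficient of variation of cycle durations.
#' @param contact_x_sd SD (m) of paw contact placement jitter.
#' @param noise List with `mult` (multiplicative envelope noise SD) and `add`
#'   (additive baseline noise SD, arbitrary units; burst amplitude is 1).
#' @param stim Stimulation train: `n_pulses`, `pulse_width_ms`, `rate_hz`,
#'   `intensity` (multiple of motor threshold), `cycle_gap_range`
#'   (inter-stimulus gap in cycles, within `[2, 4]`).
#' @param stim_nerve,stim_limb Stimulated nerve label and its limb.
#' @param reference_limb Limb whose contacts define the locomotor cycle for
#'   stimulus timing and reflex phase binning.
#' @param seed Integer seed; all generator randomness derives from it.
#' @param noiseless If `TRUE`, zero all noise sources (duration jitter,
#'   placement jitter, EMG noise) and set coupling concentrations to `Inf`.
#' @return Object of class `"session_config"` (a named list).
#' @export
session_config <- function(condition = "tied_slow",
                           left_speed = NULL, right_speed = NULL,
                           n_cycles = 360,
                           emg_sample_rate = 2000,
                           muscles = default_muscles(),
                           coupling_targets = default_coupling_targets(condition),
                           cycle_model = list(intercept = 1.05, slope = -0.5),
                           stance_model = list(intercept = 0.80, slope = -0.25),
                           duration_cv = 0.03,
                           contact_x_sd = 0.005,
                           noise = list(mult = 0.15, add = 0.05),
                           stim = list(n_pulses = 3, pulse_width_ms = 0.2,
                                       rate_hz = 300, intensity = 1.2,
                                       cycle_gap_range = c(2L, 4L)),
                           stim_nerve = "SP", stim_limb = "LH",
                           reference_limb = "LH",
                           seed = 1L,
                           noiseless = FALSE) {
  condition <- match.arg(condition, CONDITIONS)
  sp <- condition_speeds(condition)
  left_speed <- left_speed %||% unname(sp["left"])
  right_speed <- right_speed %||% unname(sp["right"])
  if (noiseless) {
    duration_cv <- 0
    contact_x_sd <- 0
    noise <- list(mult = 0, add = 0)
    coupling_targets$kappa <- Inf
  }
  cfg <- list(
    condition = condition,
    left_speed = left_speed, right_speed = right_speed,
    n_cycles = as.integer(n_cycles),
    emg_sample_rate = emg_sample_rate,
    muscles = muscles,
    coupling_targets = coupling_targets,
    cycle_model = cycle_model, stance_model = stance_model,
    duration_cv = duration_cv, contact_x_sd = contact_x_sd,
    noise = noise, stim = stim,
    stim_nerve = stim_nerve, stim_limb = stim_limb,
    reference_limb = reference_limb,
    seed = as.integer(seed)
  )
  validate_session_config(cfg)
  structure(cfg, class = "session_config")
}

validate_session_config <- function(cfg) {
  if (cfg$left_speed <= 0 || cfg$right_speed <= 0) {
    abort("Belt speeds must be positive.")
  }
  if (cfg$n_cycles < 20) abort("`n_cycles` must be at least 20.")
  if (cfg$emg_sample_rate < 1000) {
    abort("`emg_sample_rate` must be >= 1000 Hz (reflex windows span 7-60 ms).")
  }
  gr <- cfg$stim$cycle_gap_range
  if (length(gr) != 2 || gr[1] > gr[2] || gr[1] < 2 || gr[2] > 4) {
    abort("`stim$cycle_gap_range` must lie within [2, 4].")
  }
  for (v in c(cfg$left_speed, cfg$right_speed)) {
    f <- cfg$stance_model$intercept + cfg$stance_model$slope * v
    if (f <= 0 || f >= 1) {
      abort(sprintf("Stance fraction %.2f at speed %.2f m/s is outside (0, 1).", f, v))
    }
    d <- cfg$cycle_model$intercept + cfg$cycle_model$slope * v
    if (d <= 0) abort("Cycle-duration model yields a non-positive duration.")
  }
  if (any(cfg$coupling_targets$kappa < 0)) abort("Coupling kappa must be >= 0.")
  if (!cfg$reference_limb %in% LIMBS) abort("`reference_limb` must be one of LF/RF/LH/RH.")
  if (!cfg$stim_limb %in% LIMBS) abort("`stim_limb` must be one of LF/RF/LH/RH.")
  invisible(cfg)
}

#' @export
print.session_config <- function(x, ...) {
  cat(sprintf("<session_config> %s: left %.2f / right %.2f m/s, %d cycles, %g Hz EMG, seed %d\n",
              x$condition, x$left_speed, x$right_speed, x$n_cycles,
              x$emg_sample_rate, x$seed))
  invisible(x)
}

speed_cycle_duration <- function(cfg, v) {
  cfg$cycle_model$intercept + cfg$cycle_model$slope * v
}

speed_stance_fraction <- function(cfg, v) {
  cfg$stance_model$intercept + cfg$stance_model$slope * v
}

belt_speed_of <- function(cfg, limb) {
  ifelse(limb_side(limb) == "left", cfg$left_speed, cfg$right_speed)
}

#' Analysis configuration for the reflex pipeline
#'
#' @param n_bins Number of phase bins per cycle (default 10).
#' @param latency_windows_ms Named list of onset windows in ms post-stimulus
#'   for short (`1`), mid (`2`) and long (`3`) latency classes.
#' @param interlimb_short_cap_ms Crossed/homolateral/diagonal responses with
#'   onsets at or below this bound are classed short-latency (P1/N1), the
#'   minimal spino-bulbo-spinal latency.
#' @param ci_level Confidence level (percent) of the detection band around
#'   the baseline locomotor EMG.
#' @param min_stim_per_bin Minimum stimulated cycles per phase bin for
#'   detection.
#' @param min_response_ms Minimum time the stimulated average must stay
#'   outside the band to open a response.
#' @param smooth_ms Moving-average width applied before detection.
#' @param pre_ms,post_ms Extent of the stimulus-triggered window.
#' @param search_ms Onset search window post-stimulus.
#' @param alpha Significance threshold for the statistical layer.
#' @param normalization `"signed"` (default): normalize to the maximum signed
#'   net value per muscle; `"abs"`: to the maximum absolute value.
#' @param blemg_floor Minimum integrated blEMG below which a net reflex value
#'   is undefined (division guard).
#' @return Object of class `"analysis_config"`.
#' @export
analysis_config <- function(n_bins = 10L,
                            latency_windows_ms = list(`1` = c(7, 18),
                                                      `2` = c(19, 34),
                                                      `3` = c(35, 60)),
                            interlimb_short_cap_ms = 18,
                            ci_level = 97.5,
                            min_stim_per_bin = 4L,
                            min_response_ms = 3,
                            smooth_ms = 2,
                            pre_ms = 20, post_ms = 80,
                            search_ms = c(7, 60),
                            alpha = 0.05,
                            normalization = c("signed", "abs"),
                            blemg_floor = 1e-9) {
  normalization <- match.arg(normalization)
  w <- latency_windows_ms
  if (length(w) != 3 || any(diff(unlist(w)) < 0)) {
    abort("`latency_windows_ms` must be three ordered, non-overlapping windows.")
  }
  if (ci_level <= 50 || ci_level >= 100) abort("`ci_level` must be in (50, 100).")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  structure(
    list(n_bins = as.integer(n_bins), latency_windows_ms = w,
         interlimb_short_cap_ms = interlimb_short_cap_ms,
         ci_level = ci_level, min_stim_per_bin = as.integer(min_stim_per_bin),
         min_response_ms = min_response_ms, smooth_ms = smooth_ms,
         pre_ms = pre_ms, post_ms = post_ms, search_ms = search_ms,
         alpha = alpha, normalization = normalization,
         blemg_floor = blemg_floor),
    class = "analysis_config"
  )
}
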
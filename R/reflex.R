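# Quantification of stimulus-evoked cutaneous reflex responses against the
# baseline locomotor EMG (blEMG): cycle tagging, phase binning,
# stimulus-triggered averaging, response detection and latency
# classification, net reflex values and phase-modulation indexes.

#' Tag locomotor cycles as stimulated, control or excluded
#'
#' A cycle is `stimulated` when at least one stimulus falls within it
#' (half-open `[onset, next onset)`), `control` when it has no stimulus and
#' the preceding cycle was not stimulated, and `excluded` otherwise (the
#' cycle right after a stimulated one, where after-effects could linger).
#'
#' @param cycle_onsets Ordered cycle onset times (s); `n` onsets define
#'   `n - 1` cycles.
#' @param stim_times Stimulus times (s).
#' @return Character vector of length `length(cycle_onsets) - 1`.
#' @export
#' @examples
#' tag_cycles(0:6, stim_times = 3.5)
tag_cycles <- function(cycle_onsets, stim_times) {
  n <- length(cycle_onsets) - 1
  if (n < 1) abort("Need at least two cycle onsets.")
  if (is.unsorted(cycle_onsets, strictly = TRUE)) abort("Cycle onsets must be strictly increasing.")
  stimulated <- vapply(seq_len(n), function(i) {
    any(stim_times >= cycle_onsets[i] & stim_times < cycle_onsets[i + 1])
  }, logical(1))
  labels <- character(n)
  for (i in seq_len(n)) {
    labels[i] <- if (stimulated[i]) {
      "stimulated"
    } else if (i > 1 && stimulated[i - 1]) {
      "excluded"
    } else {
      "control"
    }
  }
  labels
}

#' Phase bin of a stimulus within its locomotor cycle
#'
#' The cycle is divided into `n_bins` subphases of equal duration; the bin is
#' `floor(n_bins * (t - onset) / duration)`, clamped to the last bin.
#'
#' @param stim_times Stimulus times (s).
#' @param cycle_onsets Ordered cycle onset times (s).
#' @param n_bins Number of phase bins (default 10).
#' @param allow_outside If `TRUE`, stimuli outside the cycle span give `NA`
#'   instead of an error.
#' @return Integer bins in `0:(n_bins - 1)`.
#' @export
assign_stim_phase <- function(stim_times, cycle_onsets, n_bins = 10L,
                              allow_outside = FALSE) {
  i <- findInterval(stim_times, cycle_onsets)
  outside <- i == 0 | stim_times >= cycle_onsets[length(cycle_onsets)]
  if (any(outside) && !allow_outside) {
    abort(sprintf("Stimulus at %.3f s lies outside the cycle span.",
                  stim_times[which(outside)[1]]))
  }
  frac <- (stim_times - cycle_onsets[pmax(i, 1)]) /
    (cycle_onsets[pmin(i + 1, length(cycle_onsets))] - cycle_onsets[pmax(i, 1)])
  bin <- pmin(floor(n_bins * frac), n_bins - 1L)
  bin[outside] <- NA_integer_
  as.integer(bin)
}

session_reference_onsets <- function(session) {
  ev <- limb_events(session$events, session$config$reference_limb)
  ev$time_s[ev$event == "contact"]
}

session_channel <- function(session, muscle) {
  ch <- which(session$emg$channels$muscle == muscle)
  if (length(ch) != 1) abort(sprintf("Muscle '%s' is not a unique EMG channel.", muscle))
  ch
}

# centred moving average with shrinking edges; width in samples
moving_average <- function(x, k) {
  if (k <= 1) return(x)
  half <- floor(k / 2)
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Baseline locomotor EMG (blEMG) profile
#'
#' Rectifies and time-normalizes every control cycle (cycles defined from the
#' reference limb's contacts), averages them, and reports the mean over each
#' of the 10 equal subphases together with the full normalized-time trace.
#'
#' @param session A `"gait_session"`.
#' @param config An [analysis_config()].
#' @param n_points Samples of the normalized-time trace per cycle.
#' @return Object of class `"blemg_profile"`: list with `bins` (tibble
#'   `muscle`, `bin`, `mean`), `traces` (`n_points` x muscles matrix),
#'   `n_control`, `phase` (normalized time of trace samples).
#' @export
build_blemg <- function(session, config = analysis_config(), n_points = 200L) {
  rate <- session$emg$rate_hz
  onsets <- session_reference_onsets(session)
  labels <- tag_cycles(onsets, session$stims$time_s)
  ctrl <- which(labels == "control")
  if (length(ctrl) == 0) abort("No control cycles available to build the blEMG.")
  if (length(ctrl) < 10) warn(sprintf("Only %d control cycles; blEMG will be noisy.", length(ctrl)))
  n_samples <- nrow(session$emg$signal)
  u <- (seq_len(n_points) - 1) / n_points
  traces <- matrix(0, n_points, ncol(session$emg$signal))
  used <- 0L
  for (i in ctrl) {
    idx <- round((onsets[i] + u * (onsets[i + 1] - onsets[i])) * rate) + 1L
    if (min(idx) < 1 || max(idx) > n_samples) next
    traces <- traces + abs(session$emg$signal[idx, , drop = FALSE])
    used <- used + 1L
  }
  traces <- traces / used
  bin_of <- pmin(floor(u * config$n_bins), config$n_bins - 1L)
  bins <- purrr::map_dfr(seq_len(ncol(traces)), function(ch) {
    tibble::tibble(
      muscle = session$emg$channels$muscle[ch],
      bin = 0:(config$n_bins - 1L),
      mean = as.numeric(tapply(traces[, ch], bin_of, mean))
    )
  })
  structure(
    list(bins = bins, traces = traces, n_control = used, phase = u,
         muscles = session$emg$channels$muscle),
    class = "blemg_profile"
  )
}

#' @export
print.blemg_profile <- function(x, ...) {
  cat(sprintf("<blemg_profile> %d muscles, %d control cycles\n",
              length(x$muscles), x$n_control))
  invisible(x)
}

#' Activity period and mid-activity/mid-inactivity windows of a muscle
#'
#' The activity period is the longest contiguous (circular) run of phase bins
#' whose blEMG mean exceeds `min + threshold_frac * (max - min)`. The
#' mid-activity window is the midpoint of that period plus/minus `half_width`
#' of the cycle; likewise for the inactivity period. A muscle whose bin means
#' never rise `min_relief` above their minimum (relative to the maximum) is
#' reported fully inactive with a warning.
#'
#' @param blemg A `"blemg_profile"`.
#' @param threshold_frac Fraction of the bin-mean range used as the activity
#'   threshold.
#' @param half_width Half-width of the mid windows, as a fraction of the
#'   cycle (default 0.075, i.e. +/-7.5%).
#' @param min_relief Minimum dynamic range (fraction of the maximum) for a
#'   channel to count as modulated.
#' @return Tibble with one row per muscle: activity period bounds (cycle
#'   fractions, end may exceed 1 when the period wraps), mid-activity and
#'   mid-inactivity windows, and `active` flag.
#' @export
activity_windows <- function(blemg, threshold_frac = 0.2, half_width = 0.075,
                             min_relief = 0.05) {
  purrr::map_dfr(unique(blemg$bins$muscle), function(ms) {
    x <- blemg$bins$mean[blemg$bins$muscle == ms]
    n <- length(x)
    rng <- max(x) - min(x)
    if (max(x) <= 0 || rng < min_relief * max(x)) {
      warn(sprintf("Muscle %s never crosses the activity threshold; whole cycle inactive.", ms))
      return(tibble::tibble(muscle = ms, active = FALSE,
                            active_start = NA_real_, active_end = NA_real_,
                            mid_activity_lo = NA_real_, mid_activity_hi = NA_real_,
                            mid_inactivity_lo = NA_real_, mid_inactivity_hi = NA_real_))
    }
    thr <- min(x) + threshold_frac * rng
    act <- x > thr
    run <- longest_circular_run(act)
    start <- (run$start - 1) / n
    end <- (run$start - 1 + run$length) / n   # may exceed 1 when wrapping
    mid_a <- (start + end) / 2
    inact_start <- end
    inact_end <- start + 1
    mid_i <- (inact_start + inact_end) / 2
    tibble::tibble(
      muscle = ms, active = TRUE,
      active_start = start %% 1, active_end = end,
      mid_activity_lo = (mid_a - half_width) %% 1,
      mid_activity_hi = (mid_a + half_width) %% 1,
      mid_inactivity_lo = (mid_i - half_width) %% 1,
      mid_inactivity_hi = (mid_i + half_width) %% 1
    )
  })
}

# longest run of TRUE in a circular logical vector; returns start index and length
longest_circular_run <- function(act) {
  n <- length(act)
  if (all(act)) return(list(start = 1L, length = n))
  if (!any(act)) return(list(start = NA_integer_, length = 0L))
  doubled <- c(act, act)
  r <- rle(doubled)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cand <- which(r$values & r$lengths == max(r$lengths[r$values]) & starts <= n)
  list(start = as.integer(starts[cand[1]]), length = as.integer(min(r$lengths[cand[1]], n)))
}

#' Stimulus-triggered averages and baseline bands per phase bin
#'
#' For one muscle, splits stimuli into phase bins of the reference-limb cycle
#' and builds, per bin: the rectified stimulated average around the stimulus,
#' and a baseline built from control cycles sampled at the same within-cycle
#' fractions as the bin's stimuli (so stimulated and baseline averages see
#' the same locomotor envelope). The detection band scale combines the
#' control pointwise SD with both sampling contributions
#' (`sqrt(1/n_stim + 1/n_control)`).
#'
#' @param session A `"gait_session"`.
#' @param muscle Muscle name (must be an EMG channel).
#' @param config An [analysis_config()].
#' @return Object of class `"reflex_traces"`: list with `muscle`, `relation`,
#'   `times_ms` and `bins`, a list of per-bin entries (`bin`, `n_stim`,
#'   `n_control`, `stim_avg`, `baseline`, `band_se`, `df`).
#' @export
reflex_traces <- function(session, muscle, config = analysis_config()) {
  rate <- session$emg$rate_hz
  ch <- session_channel(session, muscle)
  sig <- abs(session$emg$signal[, ch])
  n_samples <- length(sig)
  onsets <- session_reference_onsets(session)
  labels <- tag_cycles(onsets, session$stims$time_s)
  bins <- assign_stim_phase(session$stims$time_s, onsets, config$n_bins,
                            allow_outside = TRUE)
  cyc_idx <- findInterval(session$stims$time_s, onsets)
  frac <- (session$stims$time_s - onsets[pmax(cyc_idx, 1)]) /
    (onsets[pmin(cyc_idx + 1, length(onsets))] - onsets[pmax(cyc_idx, 1)])

  npre <- round(config$pre_ms / 1000 * rate)
  npost <- round(config$post_ms / 1000 * rate)
  times_ms <- (seq(-npre, npost)) / rate * 1000
  win <- seq(-npre, npost)

  ctrl <- which(labels == "control")
  ctrl_onset <- onsets[ctrl]
  ctrl_dur <- onsets[ctrl + 1] - onsets[ctrl]

  # samples that may carry evoked activity: anything within the
  # post-stimulus window of any stimulus. Baseline windows overlapping them
  # are discarded so that controls aligned near the end of a cycle cannot
  # pick up the next (stimulated) cycle's response.
  contaminated <- logical(n_samples)
  for (t0 in session$stims$time_s) {
    i0 <- round(t0 * rate) + 1L
    contaminated[max(1, i0):min(n_samples, i0 + npost)] <- TRUE
  }
  ccum <- c(0, cumsum(contaminated))
  # control windows must also stay inside the recorded gait span: outside the
  # first/last reference contact the locomotor envelope is undefined
  gait_lo <- round(onsets[1] * rate) + 1L
  gait_hi <- round(onsets[length(onsets)] * rate) + 1L
  window_clean <- function(starts) {
    inside <- starts - npre >= gait_lo & starts + npost <= gait_hi
    inside & ccum[pmin(starts + npost, n_samples) + 1] - ccum[pmax(starts - npre, 1)] == 0
  }

  per_bin <- purrr::map(0:(config$n_bins - 1L), function(b) {
    sel <- which(!is.na(bins) & bins == b)
    m <- length(sel)
    if (m == 0) {
      return(list(bin = b, n_stim = 0L, n_control = length(ctrl),
                  stim_avg = NULL, baseline = NULL, band_se = NULL, df = NA))
    }
    idx0 <- round(session$stims$time_s[sel] * rate) + 1L
    ok <- idx0 - npre >= 1 & idx0 + npost <= n_samples
    idx0 <- idx0[ok]; fr <- frac[sel][ok]
    m <- length(idx0)
    if (m == 0) {
      return(list(bin = b, n_stim = 0L, n_control = length(ctrl),
                  stim_avg = NULL, baseline = NULL, band_se = NULL, df = NA))
    }
    stim_mat <- vapply(idx0, function(i0) sig[i0 + win], numeric(length(win)))
    stim_avg <- rowMeans(stim_mat)
    # controls aligned at the same cycle fractions
    bl_sum <- numeric(length(win))
    var_sum <- numeric(length(win))
    n_c_used <- 0L
    for (j in seq_len(m)) {
      starts <- round((ctrl_onset + fr[j] * ctrl_dur) * rate) + 1L
      keep <- starts - npre >= 1 & starts + npost <= n_samples & window_clean(starts)
      starts <- starts[keep]
      if (length(starts) < 2) next
      cmat <- vapply(starts, function(i0) sig[i0 + win], numeric(length(win)))
      mu <- rowMeans(cmat)
      v <- rowSums((cmat - mu)^2) / (length(starts) - 1)
      bl_sum <- bl_sum + mu
      var_sum <- var_sum + v * (1 + 1 / length(starts))
      n_c_used <- max(n_c_used, length(starts))
    }
    if (n_c_used == 0) abort("No complete control cycles to build the reflex baseline.")
    baseline <- bl_sum / m
    band_se <- sqrt(var_sum) / m
    list(bin = b, n_stim = m, n_control = n_c_used,
         stim_avg = stim_avg, baseline = baseline, band_se = band_se,
         df = n_c_used - 1)
  })
  relation <- limb_relation(session$emg$channels$limb[ch], session$config$stim_limb)
  structure(
    list(muscle = muscle, relation = relation, condition = session$config$condition,
         rate_hz = rate, times_ms = times_ms, bins = per_bin),
    class = "reflex_traces"
  )
}

#' Detect an evoked response in a stimulus-triggered average
#'
#' Smooths the stimulated average and the baseline with a short moving
#' average, and finds the earliest run where the stimulated average leaves
#' the baseline confidence band (t-based, at the configured level) on one
#' side for at least the minimum-duration criterion, with onset inside the
#' search window. The offset is the return into the band (capped at the end
#' of the window).
#'
#' @param trace_bin One element of `reflex_traces()$bins`.
#' @param times_ms Time axis (ms relative to the stimulus).
#' @param config An [analysis_config()].
#' @return `NULL` if no response, otherwise a list with `onset_ms`,
#'   `offset_ms`, `sign` (+1/-1) and `peak_dev`.
#' @export
detect_response <- function(trace_bin, times_ms, config = analysis_config()) {
  if (is.null(trace_bin$stim_avg)) return(NULL)
  rate <- 1000 * (length(times_ms) - 1) / (times_ms[length(times_ms)] - times_ms[1])
  k <- max(1, round(config$smooth_ms / 1000 * rate))
  dev <- moving_average(trace_bin$stim_avg, k) - moving_average(trace_bin$baseline, k)
  se <- moving_average(trace_bin$band_se, k)
  floor_se <- 1e-10 * max(max(trace_bin$baseline), 1e-12)
  se <- pmax(se, floor_se)
  tcrit <- qt(1 - (1 - config$ci_level / 100) / 2, df = max(trace_bin$df, 1))
  state <- ifelse(dev > tcrit * se, 1L, ifelse(dev < -tcrit * se, -1L, 0L))
  min_run <- max(1, round(config$min_response_ms / 1000 * rate))
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cand <- which(r$values != 0L & r$lengths >= min_run &
                  times_ms[starts] >= config$search_ms[1] &
                  times_ms[starts] <= config$search_ms[2])
  if (length(cand) == 0) return(NULL)
  i <- cand[1]
  onset_i <- starts[i]
  offset_i <- min(ends[i] + 1, length(times_ms))
  seg <- dev[starts[i]:ends[i]]
  list(onset_ms = times_ms[onset_i], offset_ms = times_ms[offset_i],
       sign = r$values[i], peak_dev = seg[which.max(abs(seg))])
}

#' Classify a response by onset latency
#'
#' Excitatory (P) and inhibitory (N) responses are classed by onset latency:
#' short 7-18 ms (P1/N1), mid 19-34 ms (P2/N2), long 35-60 ms (P3/N3).
#' Responses in non-stimulated limbs (crossed, homolateral, diagonal) with
#' onsets at or below 18 ms are short-latency by definition (the minimal
#' spino-bulbo-spinal latency). Onsets below 7 ms are rejected as stimulus
#' artifacts; onsets in the unprinted gaps (18-19, 34-35 ms) go to the nearer
#' window and are flagged.
#'
#' @param onset_ms Onset latency (ms post-stimulus).
#' @param sign +1 (excitatory) or -1 (inhibitory).
#' @param relation Limb relation (see [limb_relation()]).
#' @param config An [analysis_config()].
#' @return `NULL` if rejected, otherwise list with `class` (e.g. `"P2"`),
#'   `window` index (1-3) and `gap_flagged`.
#' @export
classify_response <- function(onset_ms, sign, relation, config = analysis_config()) {
  w <- config$latency_windows_ms
  if (onset_ms < w[[1]][1] || onset_ms > w[[3]][2]) return(NULL)
  idx <- NA_integer_
  gap_flagged <- FALSE
  for (i in 1:3) {
    if (onset_ms >= w[[i]][1] && onset_ms <= w[[i]][2]) { idx <- i; break }
  }
  if (is.na(idx)) {
    # in a gap between printed windows: assign to the nearer one
    gaps <- list(c(1, 2), c(2, 3))
    for (g in gaps) {
      lo <- w[[g[1]]][2]; hi <- w[[g[2]]][1]
      if (onset_ms > lo && onset_ms < hi) {
        idx <- if (onset_ms - lo <= hi - onset_ms) g[1] else g[2]
        gap_flagged <- TRUE
      }
    }
  }
  if (relation != "homonymous" && onset_ms <= config$interlimb_short_cap_ms) idx <- 1L
  letter <- if (sign > 0) "P" else "N"
  list(class = paste0(letter, idx), window = idx, gap_flagged = gap_flagged)
}

#' Net reflex value over a response window
#'
#' Integrates the rectified stimulated average and the baseline blEMG over
#' the same post-stimulus window (trapezoidal rule) and returns
#' `(integral(stimulated) - integral(baseline)) / integral(baseline)`:
#' positive for excitation, negative for inhibition, and invariant to an
#' overall EMG scale.
#'
#' @param stim_avg,baseline Traces on the `times_ms` axis.
#' @param times_ms Time axis (ms relative to the stimulus).
#' @param window_ms Response window `c(onset, offset)` in ms.
#' @param floor Minimum baseline integral; below it the value is undefined
#'   (`NA`) with a warning.
#' @return Dimensionless net reflex value.
#' @export
net_reflex_value <- function(stim_avg, baseline, times_ms, window_ms,
                             floor = 1e-9) {
  sel <- which(times_ms >= window_ms[1] & times_ms <= window_ms[2])
  if (length(sel) < 2) abort("Response window contains fewer than two samples.")
  dt <- diff(times_ms[sel])
  integ <- function(y) sum((y[sel][-1] + y[sel][-length(sel)]) / 2 * dt)
  Ib <- integ(baseline)
  if (Ib < floor) {
    warn("Integrated blEMG below floor; net reflex value undefined.")
    return(NA_real_)
  }
  (integ(stim_avg) - Ib) / Ib
}

#' Detect, classify and quantify reflex responses for a session
#'
#' Runs the full per-muscle reflex analysis: stimulus-triggered averaging per
#' phase bin, response detection against the blEMG band, latency
#' classification and net reflex values. Bins with fewer stimulated cycles
#' than `config$min_stim_per_bin` are reported with status `"insufficient"`.
#'
#' @param session A `"gait_session"`.
#' @param config An [analysis_config()].
#' @param muscles Muscles to analyse (default: all EMG channels).
#' @return Tibble with one row per (muscle, phase bin): `condition`,
#'   `muscle`, `limb`, `relation`, `bin`, `n_stim`, `status`, `sign`,
#'   `onset_ms`, `offset_ms`, `latency_class`, `gap_flagged`, `net_value`.
#' @export
reflex_responses <- function(session, config = analysis_config(),
                             muscles = session$emg$channels$muscle) {
  purrr::map_dfr(muscles, function(ms) {
    tr <- reflex_traces(session, ms, config)
    limb <- session$emg$channels$limb[session_channel(session, ms)]
    purrr::map_dfr(tr$bins, function(tb) {
      base <- tibble::tibble(
        condition = session$config$condition, muscle = ms, limb = limb,
        relation = tr$relation, bin = tb$bin, n_stim = tb$n_stim,
        status = NA_character_, sign = NA_integer_,
        onset_ms = NA_real_, offset_ms = NA_real_,
        latency_class = NA_character_, latency_window = NA_integer_,
        gap_flagged = NA, net_value = NA_real_
      )
      if (tb$n_stim < config$min_stim_per_bin) {
        base$status <- "insufficient"
        return(base)
      }
      det <- detect_response(tb, tr$times_ms, config)
      if (is.null(det)) {
        base$status <- "none"
        return(base)
      }
      cls <- classify_response(det$onset_ms, det$sign, tr$relation, config)
      if (is.null(cls)) {
        base$status <- "artifact"
        return(base)
      }
      base$status <- "response"
      base$sign <- det$sign
      base$onset_ms <- det$onset_ms
      base$offset_ms <- det$offset_ms
      base$latency_class <- cls$class
      base$latency_window <- cls$window
      base$gap_flagged <- cls$gap_flagged
      base$net_value <- net_reflex_value(tb$stim_avg, tb$baseline, tr$times_ms,
                                         c(det$onset_ms, det$offset_ms),
                                         floor = config$blemg_floor)
      base
    })
  })
}

#' Net reflex values over a fixed window for every phase bin
#'
#' Bypasses detection and integrates over a caller-supplied post-stimulus
#' window in every bin — the route used for ground-truth recovery, where the
#' injected response window is known.
#'
#' @param session A `"gait_session"`.
#' @param muscle Muscle name.
#' @param window_ms Post-stimulus window `c(start, end)` in ms.
#' @param config An [analysis_config()].
#' @param min_stim Minimum stimulated cycles per bin (default 1).
#' @return Tibble `bin`, `n_stim`, `net_value`.
#' @export
net_reflex_profile <- function(session, muscle, window_ms,
                               config = analysis_config(), min_stim = 1L) {
  tr <- reflex_traces(session, muscle, config)
  purrr::map_dfr(tr$bins, function(tb) {
    val <- if (tb$n_stim >= min_stim && !is.null(tb$stim_avg)) {
      net_reflex_value(tb$stim_avg, tb$baseline, tr$times_ms, window_ms,
                       floor = config$blemg_floor)
    } else {
      NA_real_
    }
    tibble::tibble(bin = tb$bin, n_stim = tb$n_stim, net_value = val)
  })
}

#' Normalize reflex responses to the per-muscle maximum
#'
#' Expresses net reflex values as a percentage of the maximal signed value
#' obtained for that muscle (and response class) across all conditions and
#' phase bins. With `method = "signed"` inhibitory values stay negative,
#' which is what lets modulation indexes exceed 100% when responses change
#' sign across the cycle; `method = "abs"` normalizes to the maximal
#' absolute value instead.
#'
#' @param responses Tibble with `muscle`, `latency_window` and `net_value`
#'   (e.g. from [reflex_responses()] across conditions).
#' @param method `"signed"` (default) or `"abs"`.
#' @param by Grouping columns defining "a muscle's responses"; default
#'   muscle, relation and latency window (so excitatory and inhibitory
#'   phases of one response window pool together, as P1/N1 etc.).
#' @return `responses` with a `normalized_value` column (percent).
#' @export
normalize_responses <- function(responses, method = c("signed", "abs"),
                                by = c("muscle", "relation", "latency_window")) {
  method <- match.arg(method)
  by <- intersect(by, names(responses))
  responses |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::mutate(normalized_value = {
      v <- .data$net_value
      denom <- if (method == "signed") {
        suppressWarnings(max(v, na.rm = TRUE))
      } else {
        suppressWarnings(max(abs(v), na.rm = TRUE))
      }
      if (!is.finite(denom) || denom == 0) {
        if (all(is.na(v) | v == 0)) {
          ifelse(is.na(v), NA_real_, 0)
        } else {
          v * 100 / suppressWarnings(max(abs(v), na.rm = TRUE))
        }
      } else {
        v * 100 / denom
      }
    }) |>
    dplyr::ungroup()
}

#' Reflex modulation index per condition
#'
#' Depth of phase-dependent modulation: the largest minus the smallest
#' normalized response across the 10 phase bins of each condition. The index
#' can exceed 100% when a muscle shows excitatory responses in some phases
#' and inhibitory responses in others.
#'
#' @param normalized Tibble from [normalize_responses()] with
#'   `normalized_value`.
#' @param by Grouping columns; default muscle, relation, class and condition.
#' @return Tibble with `n_bins` (bins contributing) and `index` (percent;
#'   `NA` with fewer than two bins).
#' @export
modulation_index <- function(normalized,
                             by = c("muscle", "relation", "latency_window", "condition")) {
  by <- intersect(by, names(normalized))
  normalized |>
    dplyr::filter(!is.na(.data$normalized_value)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n_bins = dplyr::n(),
      index = if (dplyr::n() >= 2) max(.data$normalized_value) - min(.data$normalized_value) else NA_real_,
      .groups = "drop"
    )
}
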
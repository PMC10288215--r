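# Interlimb coordination: phase and gap intervals per limb coupling, and
# their circular summaries.

#' Phase interval between two limbs
#'
#' Time from the reference limb's contact to the other limb's contact,
#' divided by the reference cycle duration and expressed in degrees. 0/360
#' degrees is strict in-phase coordination; 180 degrees is strict
#' out-of-phase alternation.
#'
#' @param ref_onset Reference limb contact time (s).
#' @param cycle_duration Reference cycle duration (s).
#' @param other_contact Other limb's contact time (s), within the reference
#'   cycle.
#' @return Degrees in `[0, 360)`.
#' @export
#' @examples
#' phase_interval(0, 1, 0.5) # 180
phase_interval <- function(ref_onset, cycle_duration, other_contact) {
  if (any(cycle_duration <= 0)) abort("Cycle duration must be positive.")
  out_of_cycle <- other_contact < ref_onset | other_contact >= ref_onset + cycle_duration
  ang <- (abs(other_contact - ref_onset) / cycle_duration * 360) %% 360
  ang[out_of_cycle] <- NA_real_
  ang
}

#' Gap interval between homologous limbs
#'
#' Step length divided by the reference limb's stride length, in degrees.
#' 0/360 degrees means both paws contact the belt at the same spot; 180
#' degrees means contact half a stride length apart.
#'
#' @param step_length Step length (m).
#' @param stride_length Reference limb stride length (m), > 0.
#' @return Degrees in `[0, 360)`.
#' @export
#' @examples
#' gap_interval(0.15, 0.30) # 180
gap_interval <- function(step_length, stride_length) {
  if (any(stride_length <= 0)) abort("Stride length must be positive.")
  (step_length / stride_length * 360) %% 360
}

COUPLING_PAIRS <- list(
  forelimb    = c(reference = "LF", other = "RF"),
  hindlimb    = c(reference = "LH", other = "RH"),
  homolateral = c(reference = "LF", other = "LH"),
  diagonal    = c(reference = "LF", other = "RH")
)

#' Phase and gap intervals for a limb coupling
#'
#' The phase interval of a coupling is the time from the reference limb's
#' contact to the other limb's contact within the same reference cycle,
#' divided by the reference cycle duration and expressed in degrees
#' (0/360 = in-phase, 180 = strict alternation). The gap interval (homologous
#' couplings only) is the step length between the two paws at the other
#' limb's contact divided by the reference limb's stride length, in degrees.
#' The reference limb is the left forelimb except for the hindlimb coupling
#' (left hindlimb). Cycles where the other limb makes no contact yield `NA`.
#'
#' @param events Gait event table (see [validate_events()]).
#' @param belt_speeds Belt speeds per limb or per side (m/s).
#' @param coupling One of `"forelimb"`, `"hindlimb"`, `"homolateral"`,
#'   `"diagonal"`.
#' @param kind `"phase"` or `"gap"` (gap only for homologous couplings).
#' @return Tibble with `coupling`, `kind`, `cycle`, `angle` (degrees in
#'   `[0, 360)`).
#' @export
#' @examples
#' cfg <- session_config("tied_slow", n_cycles = 25, seed = 1)
#' ev <- simulate_gait_events(cfg)
#' head(coupling_angles(ev, session_belt_speeds_of(cfg), "forelimb", "phase"))
coupling_angles <- function(events, belt_speeds,
                            coupling = c("forelimb", "hindlimb", "homolateral", "diagonal"),
                            kind = c("phase", "gap")) {
  coupling <- match.arg(coupling)
  kind <- match.arg(kind)
  if (kind == "gap" && !coupling %in% c("forelimb", "hindlimb")) {
    abort("Gap intervals are only defined for homologous (forelimb/hindlimb) couplings.")
  }
  pair <- COUPLING_PAIRS[[coupling]]
  ref <- pair["reference"]; other <- pair["other"]
  cyc <- gait_cycles(events[events$limb == ref, ], belt_speeds)
  oth <- limb_events(events, other)
  oth_ct <- oth[oth$event == "contact", ]
  angle <- vapply(seq_len(nrow(cyc)), function(i) {
    onset <- cyc$onset[i]; dur <- cyc$cycle_duration[i]
    j <- which(oth_ct$time_s >= onset & oth_ct$time_s < onset + dur)
    if (length(j) == 0) return(NA_real_)
    j <- j[1]
    if (kind == "phase") {
      ((oth_ct$time_s[j] - onset) / dur * 360) %% 360
    } else {
      if (is.na(cyc$stride_length[i]) || cyc$stride_length[i] <= 0) {
        abort(sprintf("Reference stride length is missing or zero in cycle %d.", i))
      }
      v_ref <- resolve_belt_speed(belt_speeds, ref)
      x_ref <- limb_position(events, ref, v_ref, oth_ct$time_s[j])
      step <- abs(oth_ct$x_m[j] - x_ref)
      (step / cyc$stride_length[i] * 360) %% 360
    }
  }, numeric(1))
  tibble::tibble(coupling = coupling, kind = kind,
                 cycle = seq_len(nrow(cyc)), angle = angle)
}

#' Belt speeds of a session configuration, per limb
#' @param config A [session_config()].
#' @return Named vector `LF`, `LH`, `RF`, `RH` (m/s).
#' @export
session_belt_speeds_of <- function(config) session_belt_speeds(config)

#' All coupling angles of a session
#'
#' Phase intervals for the four limb couplings and gap intervals for the two
#' homologous couplings.
#'
#' @param session A `"gait_session"`.
#' @return Tibble `condition`, `coupling`, `kind`, `cycle`, `angle`.
#' @export
session_couplings <- function(session) {
  bs <- session_belt_speeds(session$config)
  specs <- list(
    c("forelimb", "phase"), c("hindlimb", "phase"),
    c("homolateral", "phase"), c("diagonal", "phase"),
    c("forelimb", "gap"), c("hindlimb", "gap")
  )
  purrr::map_dfr(specs, function(s) {
    coupling_angles(session$events, bs, s[1], s[2])
  }) |>
    dplyr::mutate(condition = session$config$condition, .before = 1)
}

#' Circular summary of coupling angles
#'
#' Mean direction, resultant vector length and Rayleigh test per group.
#'
#' @param data Tibble with an `angle` column (degrees).
#' @param ... Grouping columns (tidyselect), e.g. `coupling, kind, condition`.
#' @return Tibble with `n`, `mean_deg`, `r`, `rayleigh_z`, `rayleigh_p` and
#'   the temporal/spatial symmetry index of the mean (`symmetry_pct`).
#' @export
coupling_summary <- function(data, ...) {
  data |>
    dplyr::filter(!is.na(.data$angle)) |>
    dplyr::group_by(...) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_deg = circ_mean_r(.data$angle)$mean_deg,
      r = circ_mean_r(.data$angle)$r,
      rayleigh_z = rayleigh_test(.data$angle)$statistic,
      rayleigh_p = rayleigh_test(.data$angle)$p.value,
      symmetry_pct = symmetry_index(mean_deg),
      .groups = "drop"
    )
}

#' Pairwise Watson-Williams comparisons between conditions
#'
#' @param data Tibble with `angle` and a grouping column.
#' @param group Name of the grouping column (string).
#' @return Tibble `group1`, `group2`, `statistic`, `p.value`.
#' @export
coupling_condition_tests <- function(data, group = "condition") {
  data <- data[!is.na(data$angle), ]
  levels <- unique(data[[group]])
  if (length(levels) < 2) return(tibble::tibble())
  pairs <- utils::combn(levels, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(p) {
    sub <- data[data[[group]] %in% p, ]
    ww <- watson_williams(sub$angle, sub[[group]])
    tibble::tibble(group1 = p[1], group2 = p[2],
                   statistic = ww$statistic, p.value = ww$p.value)
  })
}
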
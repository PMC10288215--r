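# Spatiotemporal gait parameters from paw contact/liftoff events.

#' Validate a gait event table
#'
#' Checks that per-limb events are strictly increasing in time and alternate
#' contact -> liftoff -> contact, with every liftoff strictly inside the
#' flanking contacts.
#'
#' @param events Tibble with columns `limb`, `event` (`"contact"` or
#'   `"liftoff"`), `time_s`, `x_m`.
#' @return `events`, invisibly, or an error naming the offending limb and row.
#' @export
validate_events <- function(events) {
  req <- c("limb", "event", "time_s", "x_m")
  if (!all(req %in% names(events))) {
    abort(sprintf("Event table must have columns %s.", paste(req, collapse = ", ")))
  }
  bad <- setdiff(unique(events$event), c("contact", "liftoff"))
  if (length(bad)) abort(sprintf("Unknown event type '%s'.", bad[1]))
  for (lb in unique(events$limb)) {
    ev <- events[events$limb == lb, ]
    ev <- ev[order(ev$time_s), ]
    if (any(diff(ev$time_s) <= 0)) {
      i <- which(diff(ev$time_s) <= 0)[1]
      abort(sprintf("Limb %s: events not strictly increasing at index %d.", lb, i + 1))
    }
    types <- ev$event
    alt <- types[-1] != types[-length(types)]
    if (!all(alt)) {
      i <- which(!alt)[1]
      abort(sprintf("Limb %s: events do not alternate at index %d ('%s' follows '%s').",
                    lb, i + 1, types[i + 1], types[i]))
    }
  }
  invisible(events)
}

limb_events <- function(events, limb) {
  ev <- events[events$limb == limb, ]
  ev[order(ev$time_s), ]
}

#' Per-cycle spatiotemporal gait parameters
#'
#' One locomotor cycle runs from a paw contact to the next contact of the same
#' limb. Stance is contact to liftoff; swing is the remainder (cycle minus
#' stance). Stride length is the horizontal distance covered by the paw
#' between contact and liftoff plus the belt travel during swing. The last
#' contact of a limb opens no cycle.
#'
#' @param events Gait event table (see [validate_events()]).
#' @param belt_speeds Named vector/list of belt speeds (m/s) per limb, or per
#'   side (`left`, `right`).
#' @param stim_times Optional stimulus times (s); cycles containing a stimulus
#'   (half-open `[onset, next onset)`) are flagged `has_stimulation` so they
#'   can be excluded from kinematic summaries.
#' @return Tibble with one row per cycle: `limb`, `cycle`, `onset`,
#'   `contact_x`, `liftoff_time`, `liftoff_x`, `cycle_duration`,
#'   `stance_duration`, `swing_duration`, `stride_length`, `belt_speed`,
#'   `has_stimulation`.
#' @export
#' @examples
#' ev <- tibble::tibble(
#'   limb = "LH",
#'   event = c("contact", "liftoff", "contact", "liftoff", "contact"),
#'   time_s = c(0, 0.6, 1, 1.6, 2),
#'   x_m = c(0.1, -0.14, 0.1, -0.14, 0.1)
#' )
#' gait_cycles(ev, c(LH = 0.4))
gait_cycles <- function(events, belt_speeds, stim_times = numeric(0)) {
  validate_events(events)
  purrr::map_dfr(unique(events$limb), function(lb) {
    ev <- limb_events(events, lb)
    ct <- ev[ev$event == "contact", ]
    lo <- ev[ev$event == "liftoff", ]
    n_cycles <- nrow(ct) - 1
    if (n_cycles < 1) return(tibble::tibble())
    v <- resolve_belt_speed(belt_speeds, lb)
    out <- purrr::map_dfr(seq_len(n_cycles), function(i) {
      onset <- ct$time_s[i]
      next_onset <- ct$time_s[i + 1]
      j <- which(lo$time_s > onset & lo$time_s < next_onset)
      if (length(j) != 1) {
        abort(sprintf("Limb %s: cycle %d has %d liftoffs between contacts.", lb, i, length(j)))
      }
      cyc <- next_onset - onset
      stance <- lo$time_s[j] - onset
      swing <- cyc - stance
      stride <- if (is.na(ct$x_m[i]) || is.na(lo$x_m[j]) || is.na(v)) {
        warn(sprintf("Limb %s cycle %d: missing position or belt speed; stride is NA.", lb, i))
        NA_real_
      } else {
        abs(ct$x_m[i] - lo$x_m[j]) + v * swing
      }
      tibble::tibble(
        limb = lb, cycle = i, onset = onset,
        contact_x = ct$x_m[i], liftoff_time = lo$time_s[j], liftoff_x = lo$x_m[j],
        cycle_duration = cyc, stance_duration = stance, swing_duration = swing,
        stride_length = stride, belt_speed = v
      )
    })
    out$has_stimulation <- vapply(seq_len(nrow(out)), function(i) {
      any(stim_times >= out$onset[i] & stim_times < out$onset[i] + out$cycle_duration[i])
    }, logical(1))
    out
  })
}

resolve_belt_speed <- function(belt_speeds, limb) {
  bs <- unlist(belt_speeds)
  if (limb %in% names(bs)) return(unname(bs[limb]))
  side <- limb_side(limb)
  if (side %in% names(bs)) return(unname(bs[side]))
  NA_real_
}

#' Interpolated horizontal paw position
#'
#' Event-level reconstruction of a paw's horizontal position: during stance
#' the paw rides the belt backward at belt speed from its contact position;
#' during swing it moves linearly from the liftoff position to the next
#' contact position. Instants outside the limb's recorded span give `NA`.
#'
#' @param events Gait event table.
#' @param limb Limb code.
#' @param belt_speed Belt speed under that limb (m/s).
#' @param t Times (s) at which to evaluate.
#' @return Positions (m), `NA` outside the recorded span.
#' @export
limb_position <- function(events, limb, belt_speed, t) {
  ev <- limb_events(events, limb)
  ct <- ev[ev$event == "contact", ]
  lo <- ev[ev$event == "liftoff", ]
  vapply(t, function(ti) {
    i <- findInterval(ti, ct$time_s)
    if (i == 0 || ti > max(ev$time_s)) return(NA_real_)
    onset <- ct$time_s[i]
    j <- which(lo$time_s >= onset)
    lo_t <- if (length(j)) lo$time_s[j[1]] else Inf
    if (ti <= lo_t) {
      ct$x_m[i] - belt_speed * (ti - onset)
    } else {
      if (i + 1 > nrow(ct)) return(NA_real_)
      lo_x <- lo$x_m[j[1]]
      frac <- (ti - lo_t) / (ct$time_s[i + 1] - lo_t)
      lo_x + frac * (ct$x_m[i + 1] - lo_x)
    }
  }, numeric(1))
}

#' Step length between a leading and a trailing limb
#'
#' Horizontal distance between the two paws at stance onset (contact) of the
#' leading limb, the trailing paw's position being interpolated with
#' [limb_position()].
#'
#' @param events Gait event table.
#' @param leading,trailing Limb codes.
#' @param belt_speeds Belt speeds per limb or side.
#' @param contact_index Which contact(s) of the leading limb to use; default
#'   all.
#' @return Tibble with `time_s`, `leading_x`, `trailing_x`, `step_length` (m,
#'   absolute).
#' @export
step_length <- function(events, leading, trailing, belt_speeds,
                        contact_index = NULL) {
  ev <- limb_events(events, leading)
  ct <- ev[ev$event == "contact", ]
  if (!is.null(contact_index)) ct <- ct[contact_index, ]
  v_tr <- resolve_belt_speed(belt_speeds, trailing)
  tr_x <- limb_position(events, trailing, v_tr, ct$time_s)
  tibble::tibble(
    time_s = ct$time_s,
    leading_x = ct$x_m,
    trailing_x = tr_x,
    step_length = abs(ct$x_m - tr_x)
  )
}
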
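# Session serialization: a session directory holds config.yaml, events.csv,
# stims.csv, emg.csv + emg_channels.csv, and ground_truth.json.

TIBBLE_CONFIG_FIELDS <- c("muscles", "coupling_targets")

#' Write a session to a directory
#'
#' Writes `config.yaml`, `events.csv` (limb, event, time_s, x_m), `stims.csv`
#' (time_s, nerve, limb), `emg.csv` (one column per channel) with
#' `emg_channels.csv` (channel, muscle, limb, rate_hz), and
#' `ground_truth.json`. All values are plain text and round-trip through
#' [read_session()].
#'
#' @param session A `"gait_session"`.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- unclass(session$config)
  for (f in TIBBLE_CONFIG_FIELDS) cfg[[f]] <- as.list(cfg[[f]])
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  readr::write_csv(session$events, file.path(dir, "events.csv"))
  readr::write_csv(session$stims, file.path(dir, "stims.csv"))
  ch <- session$emg$channels
  ch$rate_hz <- session$emg$rate_hz
  readr::write_csv(ch, file.path(dir, "emg_channels.csv"))
  emg <- tibble::as_tibble(session$emg$signal, .name_repair = ~ paste0("ch", seq_along(.x)))
  readr::write_csv(emg, file.path(dir, "emg.csv"))
  gt <- session$ground_truth
  jsonlite::write_json(unclass(gt), file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

require_file <- function(dir, name) {
  path <- file.path(dir, name)
  if (!file.exists(path)) abort(sprintf("Session directory is missing '%s'.", name))
  path
}

#' Read a session from a directory
#'
#' Validates the on-disk schema: gait events must alternate and increase per
#' limb, the EMG rate must be at least 1000 Hz, the EMG matrix must have one
#' column per declared channel, and every stimulus must lie inside the
#' recording.
#'
#' @param dir Directory written by [write_session()].
#' @return A `"gait_session"`.
#' @export
read_session <- function(dir) {
  cfg_raw <- yaml::read_yaml(require_file(dir, "config.yaml"))
  for (f in TIBBLE_CONFIG_FIELDS) cfg_raw[[f]] <- tibble::as_tibble(cfg_raw[[f]])
  cfg_raw$stim$cycle_gap_range <- as.integer(cfg_raw$stim$cycle_gap_range)
  config <- structure(cfg_raw, class = "session_config")
  validate_session_config(config)

  events <- readr::read_csv(require_file(dir, "events.csv"),
                            col_types = readr::cols(
                              limb = readr::col_character(),
                              event = readr::col_character(),
                              time_s = readr::col_double(),
                              x_m = readr::col_double()
                            ))
  validate_events(events)
  stims <- readr::read_csv(require_file(dir, "stims.csv"),
                           col_types = readr::cols(
                             time_s = readr::col_double(),
                             nerve = readr::col_character(),
                             limb = readr::col_character()
                           ))
  ch <- readr::read_csv(require_file(dir, "emg_channels.csv"),
                        col_types = readr::cols(
                          channel = readr::col_integer(),
                          muscle = readr::col_character(),
                          limb = readr::col_character(),
                          rate_hz = readr::col_double()
                        ))
  rate <- unique(ch$rate_hz)
  if (length(rate) != 1) abort("Inconsistent EMG sample rates across channels.")
  if (rate < 1000) abort(sprintf("EMG sample rate %g Hz is below the 1000 Hz minimum.", rate))
  emg <- readr::read_csv(require_file(dir, "emg.csv"),
                         col_types = readr::cols(.default = readr::col_double()))
  if (ncol(emg) != nrow(ch)) {
    missing <- setdiff(paste0("ch", ch$channel), names(emg))
    abort(sprintf("EMG container truncated: channel '%s' (%s) is missing.",
                  ifelse(length(missing), missing[1], paste0("ch", ncol(emg) + 1)),
                  ch$muscle[min(nrow(ch), ncol(emg) + 1)]))
  }
  signal <- as.matrix(emg)
  dimnames(signal) <- NULL
  if (nrow(stims)) {
    t_max <- (nrow(signal) - 1) / rate
    if (any(stims$time_s < 0 | stims$time_s > t_max)) {
      abort("A stimulus time lies outside the EMG recording.")
    }
  }
  gt_raw <- jsonlite::read_json(require_file(dir, "ground_truth.json"),
                                simplifyVector = TRUE)
  gt_raw$responses <- tibble::as_tibble(gt_raw$responses)
  if (!is.list(gt_raw$responses$profile)) {
    gt_raw$responses$profile <- as.list(as.data.frame(t(gt_raw$responses$profile)))
  }
  gt_raw$responses$profile <- purrr::map(gt_raw$responses$profile, as.numeric)
  names(gt_raw$responses$profile) <- NULL
  gt_raw$activity_windows <- tibble::as_tibble(gt_raw$activity_windows)
  gt_raw$coupling_targets <- tibble::as_tibble(gt_raw$coupling_targets)
  gt_raw$stance_fractions <- unlist(gt_raw$stance_fractions)
  ground_truth <- structure(gt_raw, class = "reflex_ground_truth")

  structure(
    list(events = events, stims = stims,
         emg = list(signal = signal, rate_hz = rate,
                    channels = ch[, c("channel", "muscle", "limb")]),
         ground_truth = ground_truth, config = config),
    class = "gait_session"
  )
}
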
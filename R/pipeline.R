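# End-to-end analysis of one or more sessions (typically the four locomotor
# conditions of one animal/nerve).

#' Run the full analysis pipeline
#'
#' For each session: per-cycle spatiotemporal gait parameters (stimulated
#' cycles flagged and excluded from summaries), coupling angles with circular
#' summaries, and — when the session has stimuli — the reflex analysis
#' (detection, classification, net reflex values). Across sessions, net
#' values are normalized per muscle/class to the maximum over all conditions
#' and condensed into modulation indexes; with more than one condition,
#' Watson-Williams comparisons of coupling mean directions are added.
#'
#' @param sessions A `"gait_session"` or a list of them (one per condition).
#' @param config An [analysis_config()].
#' @param out_dir Optional directory; when given, all tables are written as
#'   CSV plus a `manifest.json` with the configuration hash and seeds.
#' @return Object of class `"reflexgait_report"`: list with `kinematics`,
#'   `couplings`, `coupling_summary`, `coupling_tests`, `responses`,
#'   `modulation`, `manifest`.
#' @export
run_pipeline <- function(sessions, config = analysis_config(), out_dir = NULL) {
  if (inherits(sessions, "gait_session")) sessions <- list(sessions)
  kinematics <- purrr::map_dfr(sessions, function(s) {
    gait_cycles(s$events, session_belt_speeds(s$config), s$stims$time_s) |>
      dplyr::mutate(condition = s$config$condition, .before = 1)
  })
  couplings <- purrr::map_dfr(sessions, session_couplings)
  coupling_sum <- coupling_summary(couplings, .data$condition, .data$coupling, .data$kind)
  coupling_tests <- if (length(sessions) > 1) {
    couplings |>
      dplyr::group_by(.data$coupling, .data$kind) |>
      dplyr::group_modify(~ coupling_condition_tests(.x, "condition")) |>
      dplyr::ungroup()
  } else {
    tibble::tibble()
  }
  responses <- purrr::map_dfr(sessions, function(s) {
    if (nrow(s$stims) == 0) {
      inform(sprintf("Session '%s' has no stimuli; reflex stages skipped.",
                     s$config$condition))
      return(tibble::tibble())
    }
    reflex_responses(s, config)
  })
  modulation <- if (nrow(responses) && any(responses$status == "response")) {
    responses |>
      dplyr::filter(.data$status == "response") |>
      normalize_responses(method = config$normalization) |>
      modulation_index()
  } else {
    tibble::tibble()
  }
  manifest <- list(
    config_hash = rlang::hash(list(analysis = unclass(config),
                                   sessions = purrr::map(sessions, ~ unclass(.x$config)))),
    seeds = purrr::map_int(sessions, ~ .x$config$seed),
    conditions = purrr::map_chr(sessions, ~ .x$config$condition),
    n_cycles = purrr::map_int(sessions, ~ .x$config$n_cycles),
    n_stimuli = purrr::map_int(sessions, ~ nrow(.x$stims))
  )
  report <- structure(
    list(kinematics = kinematics, couplings = couplings,
         coupling_summary = coupling_sum, coupling_tests = coupling_tests,
         responses = responses, modulation = modulation, manifest = manifest),
    class = "reflexgait_report"
  )
  for (nm in c("kinematics", "couplings", "coupling_summary", "coupling_tests",
               "responses", "modulation")) {
    attr(report[[nm]], "config_hash") <- manifest$config_hash
  }
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.reflexgait_report <- function(x, ...) {
  cat(sprintf("<reflexgait_report> %s\n", paste(x$manifest$conditions, collapse = ", ")))
  cat(sprintf("  %d cycles, %d coupling angles, %d response rows, hash %s\n",
              nrow(x$kinematics), nrow(x$couplings), nrow(x$responses),
              x$manifest$config_hash))
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("kinematics", "couplings", "coupling_summary", "coupling_tests",
               "responses", "modulation")) {
    tbl <- report[[nm]]
    if (nrow(tbl) == 0 && ncol(tbl) == 0) next
    readr::write_csv(tbl, file.path(out_dir, paste0(nm, ".csv")))
  }
  jsonlite::write_json(report$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
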
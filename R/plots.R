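# ggplot2 graphics for the main result types.

#' @export
autoplot.blemg_profile <- function(object, ...) {
  df <- purrr::map_dfr(seq_along(object$muscles), function(ch) {
    tibble::tibble(muscle = object$muscles[ch], phase = object$phase,
                   blemg = object$traces[, ch])
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phase, y = .data$blemg)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~muscle, scales = "free_y") +
    ggplot2::labs(x = "Normalized cycle phase", y = "Rectified EMG (a.u.)",
                  title = "Baseline locomotor EMG (blEMG)") +
    ggplot2::theme_minimal()
}

#' Circular plot of coupling angles
#'
#' Phase or gap intervals around the circumference, one point per cycle,
#' coloured by condition; straight segments mark the circular mean of each
#' condition.
#'
#' @param data Tibble with `angle` and `condition` (e.g. from
#'   [session_couplings()], filtered to one coupling/kind).
#' @return A ggplot.
#' @export
plot_coupling <- function(data) {
  data <- data[!is.na(data$angle), ]
  means <- data |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(mean_deg = circ_mean_r(.data$angle)$mean_deg,
                     r = circ_mean_r(.data$angle)$r, .groups = "drop")
  ggplot2::ggplot(data, ggplot2::aes(x = .data$angle, y = 1, colour = .data$condition)) +
    ggplot2::geom_jitter(height = 0.06, width = 0, alpha = 0.6, size = 0.8) +
    ggplot2::geom_segment(data = means,
                          ggplot2::aes(x = .data$mean_deg, xend = .data$mean_deg,
                                       y = 0, yend = .data$r, colour = .data$condition),
                          linewidth = 1) +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(0, 360), breaks = seq(0, 270, 90)) +
    ggplot2::ylim(0, 1.1) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Ten-phase panel of stimulated averages over the baseline band
#'
#' @param traces A `"reflex_traces"` object.
#' @param config The [analysis_config()] used (for the band level).
#' @return A ggplot faceted by phase bin.
#' @export
plot_reflex_traces <- function(traces, config = analysis_config()) {
  df <- purrr::map_dfr(traces$bins, function(tb) {
    if (is.null(tb$stim_avg)) return(tibble::tibble())
    tcrit <- qt(1 - (1 - config$ci_level / 100) / 2, df = max(tb$df, 1))
    tibble::tibble(bin = tb$bin, time_ms = traces$times_ms,
                   stimulated = tb$stim_avg, baseline = tb$baseline,
                   lo = tb$baseline - tcrit * tb$band_se,
                   hi = tb$baseline + tcrit * tb$band_se)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$baseline), colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$stimulated), colour = "black") +
    ggplot2::facet_wrap(~bin, nrow = 2) +
    ggplot2::labs(x = "Time after stimulus (ms)", y = "Rectified EMG (a.u.)",
                  title = sprintf("%s (%s), %s", traces$muscle, traces$relation,
                                  traces$condition)) +
    ggplot2::theme_minimal()
}

#' Bar chart of reflex modulation indexes by condition
#'
#' @param indexes Tibble from [modulation_index()].
#' @return A ggplot.
#' @export
plot_modulation_index <- function(indexes) {
  ggplot2::ggplot(indexes,
                  ggplot2::aes(x = .data$condition, y = .data$index,
                               fill = .data$condition)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(latency_class ~ muscle) +
    ggplot2::labs(x = NULL, y = "Modulation index (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none",
                   axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
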
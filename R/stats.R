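# Inferential layer: one-factor repeated-measures ANOVA, unadjusted pairwise
# comparisons, and pooling of left/right nerve datasets.

rm_wide <- function(data, value, subject, within) {
  df <- data |>
    dplyr::select(subject = {{ subject }}, within = {{ within }},
                  value = {{ value }})
  wide <- tidyr::pivot_wider(df, names_from = "within", values_from = "value")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- as.character(wide$subject)
  complete <- stats::complete.cases(mat)
  if (any(!complete)) {
    inform(sprintf("Dropping %d subject(s) with missing levels: %s",
                   sum(!complete), paste(rownames(mat)[!complete], collapse = ", ")))
    mat <- mat[complete, , drop = FALSE]
  }
  mat
}

#' One-factor repeated-measures ANOVA
#'
#' Within-subjects F test for a single factor (e.g. the 10 phase bins, or the
#' 4 locomotor conditions), computed from the standard two-way decomposition
#' with subjects as blocks. Subjects with missing levels are dropped
#' (listwise) with a message. No sphericity correction is applied by default;
#' `correction = "greenhouse-geisser"` adjusts the degrees of freedom by the
#' Greenhouse-Geisser epsilon.
#'
#' @param data Long tibble.
#' @param value,subject,within Columns (tidy-eval) holding the response,
#'   subject id and factor level.
#' @param correction `"none"` (default) or `"greenhouse-geisser"`.
#' @return Object of class `"rm_anova"` with `statistic`, `df1`, `df2`,
#'   `p.value`, `epsilon`, `n_subjects`, `n_levels`. Has [tidy()]/[glance()]
#'   methods.
#' @export
#' @examples
#' d <- tidyr::expand_grid(subject = 1:6, phase = 0:4)
#' d$y <- rnorm(nrow(d)) + d$phase / 2
#' rm_anova(d, y, subject, phase)
rm_anova <- function(data, value, subject, within,
                     correction = c("none", "greenhouse-geisser")) {
  correction <- match.arg(correction)
  Y <- rm_wide(data, {{ value }}, {{ subject }}, {{ within }})
  n <- nrow(Y); k <- ncol(Y)
  if (n < 2) abort("Repeated-measures ANOVA needs at least 2 complete subjects.")
  if (k < 2) abort("Repeated-measures ANOVA needs at least 2 factor levels.")
  grand <- mean(Y)
  ss_factor <- n * sum((colMeans(Y) - grand)^2)
  ss_subject <- k * sum((rowMeans(Y) - grand)^2)
  ss_total <- sum((Y - grand)^2)
  ss_error <- ss_total - ss_factor - ss_subject
  df1 <- k - 1
  df2 <- (n - 1) * (k - 1)
  eps <- 1
  if (correction == "greenhouse-geisser") {
    S <- stats::cov(Y)
    sbar <- mean(S)
    num <- (k * (mean(diag(S)) - sbar))^2
    den <- (k - 1) * (sum(S^2) - 2 * k * sum(rowMeans(S)^2) + k^2 * sbar^2)
    eps <- if (den > 0) max(min(num / den, 1), 1 / (k - 1)) else 1
  }
  tol <- 1e-12 * max(ss_total, 1)
  if (ss_factor <= tol) {
    Fstat <- 0; p <- 1
  } else if (ss_error <= tol) {
    Fstat <- Inf; p <- 0
  } else {
    Fstat <- (ss_factor / df1) / (ss_error / df2)
    p <- pf(Fstat, df1 * eps, df2 * eps, lower.tail = FALSE)
  }
  structure(
    list(statistic = Fstat, df1 = df1 * eps, df2 = df2 * eps, p.value = p,
         epsilon = eps, n_subjects = n, n_levels = k,
         ss = c(factor = ss_factor, subject = ss_subject, error = ss_error)),
    class = "rm_anova"
  )
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("One-factor repeated-measures ANOVA\n")
  cat(sprintf("  %d subjects x %d levels\n", x$n_subjects, x$n_levels))
  cat(sprintf("  F(%.2f, %.2f) = %.4f, p = %.4g", x$df1, x$df2, x$statistic, x$p.value))
  if (x$epsilon < 1) cat(sprintf(" (GG epsilon = %.3f)", x$epsilon))
  cat("\n")
  invisible(x)
}

#' @export
tidy.rm_anova <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df1 = x$df1, df2 = x$df2,
                 p.value = x$p.value, epsilon = x$epsilon)
}

#' @export
glance.rm_anova <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p.value,
                 n_subjects = x$n_subjects, n_levels = x$n_levels)
}

#' Unadjusted pairwise comparisons between factor levels
#'
#' Paired two-sided t tests for every pair of levels, without multiplicity
#' adjustment (the workflow follows a significant repeated-measures main
#' effect and deliberately reports raw p values). Pairs whose within-pair
#' differences are a non-zero constant (zero variance) raise an error naming
#' the pair; identical columns (all differences zero) give t = 0, p = 1.
#'
#' @inheritParams rm_anova
#' @return Tibble `level1`, `level2`, `estimate` (mean difference), `t`,
#'   `df`, `p.value`.
#' @export
pairwise_comparisons <- function(data, value, subject, within) {
  Y <- rm_wide(data, {{ value }}, {{ subject }}, {{ within }})
  levels <- colnames(Y)
  pairs <- utils::combn(levels, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(p) {
    d <- Y[, p[1]] - Y[, p[2]]
    if (sd(d) == 0) {
      if (all(d == 0)) {
        return(tibble::tibble(level1 = p[1], level2 = p[2], estimate = 0,
                              t = 0, df = length(d) - 1, p.value = 1))
      }
      abort(sprintf("Zero within-pair variance for levels '%s' vs '%s'.", p[1], p[2]))
    }
    tt <- t.test(Y[, p[1]], Y[, p[2]], paired = TRUE)
    tibble::tibble(level1 = p[1], level2 = p[2],
                   estimate = unname(tt$estimate), t = unname(tt$statistic),
                   df = unname(tt$parameter), p.value = tt$p.value)
  })
}

#' Pool left and right nerve datasets
#'
#' Left- and right-nerve stimulations of the same animal are treated as
#' separate datasets and pooled for statistics, so 8 animals stimulated on
#' both sides give up to 16 rows per muscle/response. Rows whose value is
#' missing (no evoked response in that dataset) are excluded — only evoked
#' responses are pooled.
#'
#' @param left,right Tibbles with a subject column and a value column (plus
#'   any key columns such as muscle or latency class).
#' @param value Name of the value column (string).
#' @param subject Name of the subject column (string).
#' @return Pooled tibble with an added `side` and `dataset` column, missing
#'   values removed.
#' @export
pool_nerve_datasets <- function(left, right, value = "value", subject = "subject") {
  both <- dplyr::bind_rows(
    dplyr::mutate(left, side = "left"),
    dplyr::mutate(right, side = "right")
  )
  if (nrow(both) == 0) {
    return(dplyr::mutate(both, dataset = character(0)))
  }
  both |>
    dplyr::mutate(dataset = paste(.data[[subject]], .data$side, sep = "_")) |>
    dplyr::filter(!is.na(.data[[value]]))
}
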
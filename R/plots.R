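# Figure helpers: trend curves before (dashed) and after (solid) imputation.

#' Plot age-standardized rate trends before and after imputation
#'
#' Line plot of the ASR by calendar year, one panel per sex, coloured by
#' histologic class: dashed lines are the rates from cases with known
#' histology, solid lines the pooled rates after multiple imputation (with a
#' 95% probability-interval ribbon).
#'
#' @param asr The `asr` tibble of a `histmi_report` (columns `stage`, `sex`,
#'   `class`, `year`, `asr`, and `asr_lo`/`asr_hi` for the after stage).
#' @return A ggplot object.
#' @export
plot_asr_trends <- function(asr) {
  require_columns(asr, c("stage", "sex", "class", "year", "asr"), "asr")
  p <- ggplot2::ggplot(asr, ggplot2::aes(x = .data$year, y = .data$asr,
                                         colour = .data$class,
                                         linetype = .data$stage))
  if (all(c("asr_lo", "asr_hi") %in% names(asr))) {
    p <- p + ggplot2::geom_ribbon(
      data = asr |> filter(.data$stage == "after", !is.na(.data$asr_lo)),
      ggplot2::aes(ymin = .data$asr_lo, ymax = .data$asr_hi,
                   fill = .data$class),
      alpha = 0.15, colour = NA)
  }
  p +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::scale_linetype_manual(values = c(before = "dashed",
                                              after = "solid")) +
    ggplot2::facet_wrap(~sex) +
    ggplot2::labs(x = "Year of diagnosis",
                  y = "ASR per 100,000 (world standard)",
                  colour = "Histology", fill = "Histology",
                  linetype = "Imputation") +
    ggplot2::theme_minimal()
}

#' Plot case-count trends before and after imputation
#'
#' @param case_counts The `case_counts` tibble of a `histmi_report`.
#' @return A ggplot object.
#' @export
plot_case_counts <- function(case_counts) {
  require_columns(case_counts, c("stage", "sex", "class", "year", "events"),
                  "case_counts")
  ggplot2::ggplot(case_counts,
                  ggplot2::aes(x = .data$year, y = .data$events,
                               colour = .data$class,
                               linetype = .data$stage)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::scale_linetype_manual(values = c(before = "dashed",
                                              after = "solid")) +
    ggplot2::facet_wrap(~sex) +
    ggplot2::labs(x = "Year of diagnosis", y = "Number of cases",
                  colour = "Histology", linetype = "Imputation") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.histmi_report <- function(object, which = c("asr", "counts"), ...) {
  which <- match.arg(which)
  switch(which,
         asr = plot_asr_trends(object$asr),
         counts = plot_case_counts(object$case_counts))
}

#' @export
autoplot.histmi_apc <- function(object, ...) {
  eff <- tidy(object)
  ggplot2::ggplot(eff, ggplot2::aes(x = .data$value, y = .data$estimate)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~effect, scales = "free") +
    ggplot2::labs(x = NULL, y = "Rate per 100,000 (age) / rate ratio") +
    ggplot2::theme_minimal()
}
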
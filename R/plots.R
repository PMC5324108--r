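#' Plot projected cumulative-incidence curves
#'
#' One line per relative risk score, faceted by sex.
#'
#' @param object A [project_cumulative_risk()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot crc_projection
#' @export
autoplot.crc_projection <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$age,
                                       y = .data$cum_risk_per100,
                                       colour = factor(.data$rs))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$sex)) +
    ggplot2::labs(x = "Age (years)", y = "Cumulative risk per 100",
                  colour = "Risk score") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.crc_projection
#' @param projection A [project_cumulative_risk()] result.
#' @export
plot_projection <- function(projection, ...) autoplot(projection, ...)

#' Plot the distribution of a risk score in cases and controls
#'
#' @param data A cohort tibble with the score and `case_status`.
#' @param score Column (tidy-eval) holding the score (e.g. `ers` or `grs`).
#' @param binwidth Histogram bin width (1 suits allele or factor counts).
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(data, score, binwidth = 1) {
  ggplot2::ggplot(data, ggplot2::aes(x = {{ score }},
                                     fill = .data$case_status)) +
    ggplot2::geom_histogram(
      ggplot2::aes(y = ggplot2::after_stat(.data$density)),
      binwidth = binwidth, position = "dodge"
    ) +
    ggplot2::labs(y = "Proportion", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot individual and cumulative AUROC contributions
#'
#' @param curve A [cumulative_auroc_curve()] tibble.
#' @return A ggplot object.
#' @export
plot_cumulative_auroc <- function(curve) {
  long <- tidyr::pivot_longer(curve, c("individual_auroc",
                                       "cumulative_auroc"),
                              names_to = "kind", values_to = "auroc")
  long$variable <- factor(long$variable, levels = curve$variable)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$auroc, y = .data$variable,
                                     colour = .data$kind,
                                     group = .data$kind)) +
    ggplot2::geom_path() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "AUROC", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot positive predictive value by age range and cut-off
#'
#' @param ppv_table A [ppv_by_age()] tibble.
#' @return A ggplot object.
#' @export
plot_ppv_by_age <- function(ppv_table) {
  ggplot2::ggplot(ppv_table,
                  ggplot2::aes(x = .data$decade, y = .data$ppv,
                               colour = factor(.data$cutoff),
                               group = factor(.data$cutoff))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$sex)) +
    ggplot2::labs(x = "Age range", y = "Positive predictive value",
                  colour = "Risk-score cutoff") +
    ggplot2::theme_minimal()
}
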
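#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_step
#'   geom_abline geom_vline geom_histogram facet_wrap labs theme_minimal
#'   scale_fill_brewer scale_colour_brewer position_identity
NULL

#' @export
ggplot2::autoplot

#' ROC curve for a Liu cut-point fit
#'
#' Plots the empirical ROC (in the low-score-positive orientation) with the
#' chosen operating point marked.
#'
#' @param object A `liu_cutpoint` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.liu_cutpoint <- function(object, ...) {
  sweep <- object$sweep
  chosen <- sweep[sweep$threshold == object$threshold, ]
  ggplot(sweep, aes(x = .data$fpr, y = .data$sensitivity)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    geom_step(direction = "hv") +
    geom_point(data = chosen, colour = "red", size = 2) +
    labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf(
        "Liu cut-point: score < %s (sens %.2f, spec %.2f, AUC %.2f)",
        format(object$threshold), object$sensitivity,
        object$specificity, object$auc
      )
    ) +
    theme_minimal()
}

#' Score distributions and estimated cut-offs for a study report
#'
#' Histograms of the global Brief-HINE score by outcome group, faceted by
#' assessment age, with the per-age estimated cut-off drawn as a vertical
#' line.
#'
#' @param object A `bhine_study` object from [run_study()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bhine_study <- function(object, ...) {
  scores <- object$screening |>
    mutate(age = factor(paste0(.data$age_months, " months"),
      levels = paste0(hine_ages(), " months")
    ))
  cuts <- object$cutoffs |>
    mutate(age = factor(paste0(.data$age_months, " months"),
      levels = paste0(hine_ages(), " months")
    ))
  ggplot(scores, aes(x = .data$global_score, fill = .data$risk_class)) +
    geom_histogram(binwidth = 1, position = position_identity(), alpha = 0.7) +
    geom_vline(
      data = cuts[!is.na(cuts$threshold), ],
      aes(xintercept = .data$threshold), linetype = "dashed"
    ) +
    facet_wrap(~age) +
    scale_fill_brewer(palette = "Set1") +
    labs(
      x = "Global Brief-HINE score", y = "Exams", fill = NULL,
      title = "Global scores by age with estimated cut-offs"
    ) +
    theme_minimal()
}

#' Warning-sign prevalence plot
#'
#' Percentage of exams with more than k warning signs, by group and age.
#'
#' @param prevalence Output of [warning_prevalence()] (or the
#'   `warning_prevalence` element of a study report).
#' @return A ggplot object.
#' @export
plot_warning_prevalence <- function(prevalence) {
  ggplot(
    prevalence,
    aes(
      x = .data$k, y = .data$pct,
      colour = .data$group, group = .data$group
    )
  ) +
    geom_line() +
    geom_point() +
    facet_wrap(~age_months, labeller = ggplot2::label_both) +
    scale_colour_brewer(palette = "Dark2") +
    labs(
      x = "k (warning signs)", y = "% of exams with more than k",
      colour = NULL
    ) +
    theme_minimal()
}
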
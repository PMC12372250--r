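#' Box plot of classifier scores before and after intervention
#'
#' @param patients A per-patient tibble with `baseline_score` and
#'   `best_score` columns (e.g. `tidy(run_pipeline(...))`), or a
#'   `run_report`.
#' @return A ggplot object.
#' @export
plot_score_shift <- function(patients) {
  if (inherits(patients, "run_report")) patients <- patients$patients
  long <- tidyr::pivot_longer(
    patients[c("baseline_score", "best_score")],
    dplyr::everything(), names_to = "stage", values_to = "score"
  ) |>
    dplyr::mutate(stage = factor(.data$stage, c("baseline_score", "best_score"),
                                 c("before", "after")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stage, y = .data$score,
                                     fill = .data$stage)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "classifier score",
                  title = "Scores before and after in silico intervention") +
    ggplot2::theme_minimal()
}

#' Box plot of MAKE incidence rates before and after intervention
#'
#' @param patients A per-patient tibble with `rate_before` and `rate_after`
#'   columns, or a `run_report`.
#' @return A ggplot object.
#' @export
plot_rate_shift <- function(patients) {
  if (inherits(patients, "run_report")) patients <- patients$patients
  long <- tidyr::pivot_longer(
    patients[c("rate_before", "rate_after")],
    dplyr::everything(), names_to = "stage", values_to = "rate"
  ) |>
    dplyr::mutate(stage = factor(.data$stage, c("rate_before", "rate_after"),
                                 c("before", "after")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stage, y = .data$rate,
                                     fill = .data$stage)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "MAKE incidence rate / 100 person-years",
                  title = "Incidence rate before and after in silico intervention") +
    ggplot2::theme_minimal()
}

#' Bar chart of optimal-regimen frequencies
#'
#' @param freq Output of [tabulate_optimal_regimens()] (or a `run_report`).
#' @param top_n Show at most this many regimens.
#' @return A ggplot object.
#' @export
plot_regimen_frequency <- function(freq, top_n = 20L) {
  if (inherits(freq, "run_report")) freq <- freq$regimen_freq
  freq <- head(freq, top_n)
  ggplot2::ggplot(freq, ggplot2::aes(x = .data$n_patients,
                                     y = stats::reorder(.data$regimen,
                                                        .data$n_patients))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "patients with this predicted optimum", y = NULL,
                  title = "Predicted optimal regimens") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.regimen_optimization <- function(object, ...) plot_score_shift(object$best)

#' @export
autoplot.run_report <- function(object, ...) plot_rate_shift(object)
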
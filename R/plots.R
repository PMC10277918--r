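#' Kaplan-Meier plot of a survival comparison
#'
#' Step curves of recurrence-free survival per group, with the log-rank
#' p-value and "patients (events)" counts in the subtitle.
#'
#' @param object An `imc_survfit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.imc_survfit <- function(object, ...) {
  d <- tidy(object)
  origin <- d |>
    dplyr::distinct(.data$group) |>
    dplyr::mutate(time = 0, survival = 1)
  d <- dplyr::bind_rows(origin, d[, c("group", "time", "survival")]) |>
    dplyr::arrange(.data$group, .data$time)
  legend <- paste(object$groups$group, object$groups$label, collapse = ", ")
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$survival,
                                  colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Months since primary treatment",
      y = "Recurrence-free survival",
      colour = NULL,
      subtitle = sprintf("log-rank p = %.3g; patients (events): %s",
                         object$p_value, legend)
    ) +
    ggplot2::theme_minimal()
}

#' MEM heatmap
#'
#' Cluster-by-marker heatmap of signed enrichment scores in \[-10, 10\].
#'
#' @param object An `imc_mem` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.imc_mem <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$marker, factor(.data$cluster),
                                  fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-10, 10)) +
    ggplot2::labs(x = NULL, y = "Cluster", fill = "MEM") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' Abundance comparison plot
#'
#' Per-cluster median fractions in the two outcome groups, with flagged
#' clusters highlighted.
#'
#' @param object An `imc_abundance` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.imc_abundance <- function(object, ...) {
  d <- tidy(object) |>
    tidyr::pivot_longer(c("median_nonrecurrent", "median_recurrent"),
                        names_to = "group", values_to = "median_fraction") |>
    dplyr::mutate(group = sub("median_", "", .data$group))
  ggplot2::ggplot(d, ggplot2::aes(factor(.data$cluster),
                                  .data$median_fraction,
                                  fill = .data$group,
                                  alpha = .data$significant)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.4),
                                guide = "none") +
    ggplot2::labs(x = "Cluster", y = "Median per-patient fraction",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Per-patient cluster composition plot
#'
#' Stacked per-patient cluster fractions, split by outcome group.
#'
#' @param fractions Tibble `patient_id`, `cluster`, `fraction`.
#' @param outcome Tibble `patient_id`, `recurrent`.
#' @return A ggplot.
#' @export
plot_composition <- function(fractions, outcome) {
  d <- dplyr::inner_join(fractions, outcome, by = "patient_id") |>
    dplyr::mutate(group = ifelse(.data$recurrent == 1, "recurrent",
                                 "non-recurrent"))
  ggplot2::ggplot(d, ggplot2::aes(.data$patient_id, .data$fraction,
                                  fill = factor(.data$cluster))) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(. ~ group, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = "Fraction of cells", fill = "Cluster") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
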
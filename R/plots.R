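# ggplot2 displays for the result tables.

#' Plot match rates by group
#'
#' Bar chart of the per-group percentage of patients with at least one
#' matching donor, faceted by loci set when several are present.
#'
#' @param object A `"hla_grouped_rates"` tibble from
#'   [grouped_match_rates()] (rows from several loci sets may be bound
#'   together).
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.hla_grouped_rates <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$group),
                                        y = 100 * .data$rate)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = unique(df$grouping)[1],
                  y = "% with at least one match") +
    ggplot2::theme_minimal()
  if ("loci_set" %in% names(df) && length(unique(df$loci_set)) > 1) {
    p <- p + ggplot2::facet_wrap(~loci_set)
  }
  p
}

#' Plot donor self-identification composition
#'
#' Stacked bar chart of the average donor category frequencies per
#' patient group (the average-of-individual-averages estimator).
#'
#' @param composition Output of [donor_composition()].
#' @return A ggplot object.
#' @export
plot_donor_composition <- function(composition) {
  ggplot2::ggplot(composition,
                  ggplot2::aes(x = factor(.data$group), y = .data$share,
                               fill = .data$donor_self_id)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = unique(composition$grouping)[1],
                  y = "mean donor category frequency",
                  fill = "donor self-ID") +
    ggplot2::theme_minimal()
}

#' Plot ancestry recovery
#'
#' Scatter of estimated versus true African ancestry proportions, for
#' checking the supervised estimator on simulated individuals.
#'
#' @param cohort Cohort tibble with a `q_afr` column.
#' @param estimates Estimate tibble with `id` and `q_afr_hat` (from
#'   [estimate_ancestry_all()] bound to ids).
#' @return A ggplot object.
#' @export
plot_ancestry_recovery <- function(cohort, estimates) {
  df <- dplyr::inner_join(cohort, estimates, by = "id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$q_afr, y = .data$q_afr_hat)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "true African ancestry",
                  y = "estimated African ancestry") +
    ggplot2::theme_minimal()
}
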
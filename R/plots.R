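#' Plot a mutation landscape summary
#'
#' Bar panels of counts by variant classification, variant type and SNV
#' class, plus the per-sample nonsilent burden distribution.
#'
#' @param object A `neo_landscape` from [summarize_landscape()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot neo_landscape
#' @export
autoplot.neo_landscape <- function(object, ...) {
  panels <- bind_rows(
    dplyr::transmute(object$classification_counts, panel = "classification",
                     category = .data$variant_classification, n = .data$n),
    dplyr::transmute(object$type_counts, panel = "variant type",
                     category = .data$variant_type, n = .data$n),
    dplyr::transmute(object$snv_class_counts, panel = "SNV class",
                     category = .data$snv_class, n = .data$n)
  )
  ggplot2::ggplot(panels, ggplot2::aes(x = stats::reorder(.data$category,
                                                          -.data$n),
                                       y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = "mutations") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot neoantigen load against mutation burden
#'
#' Scatter of per-sample neoantigen count versus nonsilent mutation count
#' with a linear trend; the Spearman correlation between the two is the
#' cohort-level association the load analysis quantifies.
#'
#' @param object A `neo_load` table from [neoantigen_load()].
#' @param colour_by Optional metadata column to colour points by (e.g.
#'   `"age_group"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot neo_load
#' @export
autoplot.neo_load <- function(object, colour_by = NULL, ...) {
  aes <- if (is.null(colour_by)) {
    ggplot2::aes(x = .data$n_nonsilent, y = .data$n_neoantigens)
  } else {
    ggplot2::aes(x = .data$n_nonsilent, y = .data$n_neoantigens,
                 colour = .data[[colour_by]])
  }
  ggplot2::ggplot(as_tibble(object), aes) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey30", linewidth = 0.5) +
    ggplot2::labs(x = "nonsilent mutations", y = "neoantigens") +
    ggplot2::theme_minimal()
}

#' Plot cumulative panel coverage
#'
#' Step curve of the fraction of cohort samples covered as panel members
#' are added in greedy order.
#'
#' @param panel Panel tibble from [select_panel_greedy()].
#' @param n_cohort Total number of cohort samples (the coverage
#'   denominator).
#' @return A ggplot object.
#' @export
plot_panel_coverage <- function(panel, n_cohort) {
  df <- mutate(panel, coverage = .data$n_covered_cum / n_cohort)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$coverage)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%",
                                                             100 * x)) +
    ggplot2::labs(x = "panel size", y = "cohort coverage") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
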
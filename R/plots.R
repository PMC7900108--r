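# ggplot2 display helpers for the main result types.

#' Bar plot of covariate-adjusted group means
#'
#' Bars at the adjusted means with whiskers at the confidence
#' intervals, one bar per group.
#'
#' @param object An `adjusted_means` object from
#'   [adjusted_group_means()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot adjusted_means
#' @export
autoplot.adjusted_means <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$group, y = .data$estimate)) +
    ggplot2::geom_col(fill = "grey70", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$conf_low, ymax = .data$conf_high),
      width = 0.15
    ) +
    ggplot2::labs(
      x = NULL, y = "adjusted mean",
      caption = sprintf("whiskers: %.0f%% confidence intervals",
                        100 * attr(object, "conf_level"))
    ) +
    ggplot2::theme_minimal()
}

#' Per-node F statistics for one measure
#'
#' Dot plot of the omnibus F across nodes for one nodal measure, with
#' FDR-surviving nodes highlighted.
#'
#' @param results Tibble from [run_nodal_group_analysis()].
#' @param measure Nodal measure to display (e.g. `"strength"`).
#' @param alpha FDR threshold used for highlighting.
#' @return A ggplot.
#' @export
plot_nodal_f <- function(results, measure = "strength", alpha = 0.05) {
  d <- results %>%
    filter(.data$scope == "nodal", .data$measure == !!measure,
           !is.na(.data$f)) %>%
    mutate(node = factor(.data$node, levels = .data$node),
           survives = !is.na(.data$p_fdr) & .data$p_fdr < alpha)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$node, y = .data$f,
                                  colour = .data$survives)) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey55", `TRUE` = "firebrick"),
      name = sprintf("FDR < %.2g", alpha)
    ) +
    ggplot2::labs(x = NULL, y = "partial F",
                  title = paste("group difference:", measure)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(
      angle = 90, vjust = 0.5, hjust = 1, size = 5
    ))
}

#' Scatter plot of a brain-behaviour association
#'
#' Covariate-adjusted score against a covariate-adjusted network
#' measure within one group, with the least-squares fit line — the
#' visual counterpart of a partial correlation.
#'
#' @param metrics Long metric table.
#' @param scores Score table (`subject_id` + score columns).
#' @param design Subject table.
#' @param group Group level to display.
#' @param score Score column name.
#' @param measure,node Feature to display (`node = NA` for global).
#' @param covariates Covariates removed from both axes.
#' @return A ggplot.
#' @export
plot_association <- function(metrics, scores, design, group, score,
                             measure, node = NA,
                             covariates = c("age", "sex", "education")) {
  design <- validate_design(design, covariates)
  dsub <- design[design$group == group, , drop = FALSE]
  wide <- align_metrics(metrics, design)
  scope <- if (is.na(node)) "global" else "nodal"
  m <- feature_values(wide, scope, measure, node, dsub$subject_id)
  s <- scores[[score]][match(dsub$subject_id, scores$subject_id)]
  ok <- is.finite(m) & is.finite(s)
  xm <- cbind(1, as.matrix(dsub[ok, covariates, drop = FALSE]))
  d <- tibble(
    measure_adj = stats::lm.fit(xm, m[ok])$residuals,
    score_adj = stats::lm.fit(xm, s[ok])$residuals
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$measure_adj,
                                  y = .data$score_adj)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(
      x = paste0("adjusted ", measure, if (!is.na(node)) paste0(" (", node, ")")),
      y = paste("adjusted", score),
      title = group
    ) +
    ggplot2::theme_minimal()
}
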
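#' Plot whole-genome against subgenome breeding values
#'
#' One panel per subgenome (or interaction) term, each line a point, with
#' dotted lines at the upper `q`-quantile of both axes — the parental-candidate
#' view: lines beyond the vertical line are candidates on the subgenome value,
#' beyond the horizontal line on the whole-genome value.
#'
#' @param object An [assemble_effects()] table.
#' @param terms Effect columns to plot against the whole-genome value;
#'   defaults to all genetic terms.
#' @param q Quantile for the dotted reference lines (default 0.95).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.effect_table <- function(object, terms = NULL, q = 0.95, ...) {
  if (is.null(terms)) terms <- attr(object, "terms")
  long <- tidyr::pivot_longer(object[c("line_id", "whole_genome", terms)],
                              dplyr::all_of(terms),
                              names_to = "term", values_to = "sgebv")
  qs <- dplyr::summarise(dplyr::group_by(long, .data$term),
                         xq = stats::quantile(.data$sgebv, q),
                         yq = stats::quantile(.data$whole_genome, q))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sgebv, y = .data$whole_genome)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(data = qs, ggplot2::aes(xintercept = .data$xq),
                        linetype = "dotted") +
    ggplot2::geom_hline(data = qs, ggplot2::aes(yintercept = .data$yq),
                        linetype = "dotted") +
    ggplot2::facet_wrap(~term, scales = "free_x") +
    ggplot2::labs(x = "subgenome / interaction effect (SGEBV)",
                  y = "whole-genome effect (GEBV)")
}

#' Plot variance components of a REML fit
#'
#' Point estimates with +/- 2 standard-error bars from the inverse
#' average-information matrix; boundary components are marked.
#'
#' @param object A [fit_reml()] result.
#' @param include_residual Show the residual component too.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reml_fit <- function(object, include_residual = FALSE, ...) {
  td <- tidy.reml_fit(object)
  if (!include_residual) td <- dplyr::filter(td, .data$term != "residual")
  td$term <- factor(td$term, levels = td$term)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$estimate - 2 * .data$std.error,
      ymax = .data$estimate + 2 * .data$std.error,
      shape = .data$boundary)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 4),
                                guide = "none") +
    ggplot2::labs(x = NULL, y = "variance component (trait-SD^2)")
}

#' Plot per-replicate cross-validation accuracies
#'
#' @param object A [cross_validate()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_result <- function(object, ...) {
  td <- tidy.cv_result(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$model, y = .data$accuracy)) +
    ggplot2::geom_boxplot(width = 0.3, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.05, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = "prediction accuracy (r)")
}

#' Plot the subgenome-kernel collinearity diagnostic
#'
#' Correlation of subgenome kernel entries against the number of removed
#' principal components; the elbow where the curves level off is the usual
#' choice of `k`.
#'
#' @param profile Output of [collinearity_profile()].
#' @return A ggplot object.
#' @export
plot_collinearity <- function(profile) {
  profile$pair <- paste(profile$kernel_1, profile$kernel_2, sep = "-")
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$k, y = .data$correlation,
                                        colour = .data$pair)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "principal components removed (k)",
                  y = "kernel correlation", colour = NULL)
}
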
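#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the score distribution across diagnostic groups
#'
#' Group means with mean +/- SD error bars, annotated with the overall ANOVA
#' F-test p-value - the standard figure for a score-by-group comparison.
#'
#' @param object A `grs_anova` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot grs_anova
#' @export
autoplot.grs_anova <- function(object, ...) {
  stats_df <- object$group_stats
  ggplot2::ggplot(stats_df, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey75", colour = "grey25", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      width = 0.15
    ) +
    ggplot2::labs(
      x = NULL, y = "Genetic risk score (mean ± SD)",
      subtitle = sprintf("ANOVA F(%d, %d) = %.2f, p = %.3g",
                         object$df[1L], object$df[2L], object$f_statistic,
                         object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a cutoff scan
#'
#' Relative case:control enrichment ratio against the score threshold, with
#' the full-sample reference ratio of 1 marked. Thresholds with an infinite
#' or undefined ratio are dropped from the line.
#'
#' @param object A `grs_cutoff_scan` tibble from [cutoff_scan()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot grs_cutoff_scan
#' @export
autoplot.grs_cutoff_scan <- function(object, ...) {
  d <- object[object$ratio_flag == "ok", ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$threshold,
                                  y = .data$relative_ratio)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "GRS cutoff (score ≥ threshold)",
      y = "Relative ratio of cases to controls"
    ) +
    ggplot2::theme_minimal()
}
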
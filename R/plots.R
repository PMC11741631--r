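#' Plot a grouped breakdown report
#'
#' Horizontal bars of avoidance (EGP millions) per group, annotated with
#' each group's share of interventions.
#'
#' @param object A `dtp_report` from [grouped_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dtp_report
#' @export
autoplot.dtp_report <- function(object, ...) {
  df <- tidy_results(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$avoidance_egp / 1e6,
    y = stats::reorder(.data$group, .data$avoidance_egp)
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%.1f%% of DTPs", .data$share_count_pct)),
      hjust = -0.05, size = 3
    ) +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(mult = c(0, 0.2))) +
    ggplot2::labs(
      x = "Cost avoidance (EGP millions)", y = NULL,
      title = paste("Cost avoidance by", attr(object, "by"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot the per-record net-avoidance distribution
#'
#' @param object A `dtp_avoidance` from [cost_avoidance()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dtp_avoidance
#' @export
autoplot.dtp_avoidance <- function(object, ...) {
  df <- tidy_results(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$net_avoidance)) +
    ggplot2::geom_histogram(bins = 50, fill = "steelblue", colour = "white") +
    ggplot2::scale_x_continuous(labels = function(x) sprintf("%.0fk", x / 1e3)) +
    ggplot2::labs(
      x = "Net cost avoidance per intervention (EGP, thousands)",
      y = "Interventions",
      title = paste("Net cost avoidance,", attr(object, "method"), "method")
    ) +
    ggplot2::theme_minimal()
}

#' Plot a yearly ROI series
#'
#' @param series A tibble from [roi_series()].
#' @return A ggplot object.
#' @export
plot_roi_series <- function(series) {
  ggplot2::ggplot(series, ggplot2::aes(x = .data$year, y = .data$roi)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "ROI (ratio)",
                  title = "Return on investment by calendar year") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
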
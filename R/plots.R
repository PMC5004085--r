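# ggplot2 views of the result types.  All plots are built on the summary
# tibbles; nothing in the analysis depends on rendering.

#' @importFrom ggplot2 ggplot aes geom_col geom_line geom_point labs
#'   facet_wrap position_dodge autoplot
NULL

#' Plot a family-size tabulation
#' @param object An `hco_family_sizes` tibble.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.hco_family_sizes <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("total", "noninterrupted"),
                              names_to = "kind", values_to = "n")
  ggplot(long, aes(x = factor(.data$size), y = .data$n, fill = .data$kind)) +
    geom_col(position = position_dodge()) +
    labs(x = "family size (members)", y = "families", fill = NULL)
}

#' Plot classified family curves
#' @param object An `hco_sensitivity` object.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.hco_sensitivity <- function(object, ...) {
  long <- object |>
    mutate(.fam = dplyr::row_number()) |>
    select(".fam", "class", "x", "y") |>
    tidyr::unnest(c("x", "y"))
  ggplot(long, aes(x = .data$x, y = .data$y, group = .data$.fam,
                   colour = .data$class)) +
    geom_line(alpha = 0.5) +
    facet_wrap(~class) +
    labs(x = "conductance fraction", y = "characteristic",
         colour = "sensitivity")
}

#' Plot period histograms per parameter value
#'
#' @param hist A [period_histograms()] result.
#' @return A ggplot object (one panel per parameter value).
#' @export
plot_period_histograms <- function(hist) {
  ggplot(hist, aes(x = .data$bin + 0.5, y = .data$n)) +
    geom_col(width = 0.9) +
    facet_wrap(~by_value) +
    labs(x = "period (s)", y = "instances")
}

#' Plot a trace pair
#'
#' @param pair A trace-pair tibble (`time`, `v_a`, `v_b`).
#' @return A ggplot object with the two cells stacked.
#' @export
plot_trace_pair <- function(pair) {
  long <- tidyr::pivot_longer(as_tibble(pair), c("v_a", "v_b"),
                              names_to = "cell", values_to = "v")
  ggplot(long, aes(x = .data$time, y = .data$v)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~cell, ncol = 1) +
    labs(x = "time (s)", y = "membrane potential (mV)")
}
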
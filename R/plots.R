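#' Plot an outcome frequency against a condition variable
#'
#' Point-and-ribbon plot of one outcome's relative frequency (default
#' `Resist`) against a condition column of a [bootstrap_ci()] summary,
#' with its bootstrap confidence band.
#'
#' @param summary a summary `data.frame` from [bootstrap_ci()].
#' @param x name of the condition column for the x axis (e.g. `"U"`,
#'   `"E"`).
#' @param outcome outcome to plot (default `"Resist"`).
#' @return A ggplot object.
#' @export
plot_resistance <- function(summary, x = "U", outcome = "Resist") {
  df <- summary[summary$outcome == outcome, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[x]], y = .data$freq)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lower,
                                      ymax = .data$ci_upper),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = x, y = paste(outcome, "frequency")) +
    ggplot2::theme_classic()
}

#' Plot outcome frequencies across richness bins
#'
#' One line per invasion outcome against the upper edge of each
#' pre-invasion richness bin, with bootstrap confidence bands.
#'
#' @param curve a summary from [richness_resistance_curve()].
#' @return A ggplot object.
#' @export
plot_richness_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$bin_upper, y = .data$freq,
                                      colour = .data$outcome,
                                      fill = .data$outcome)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lower,
                                      ymax = .data$ci_upper),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "resident richness (bin upper edge)",
                  y = "outcome frequency") +
    ggplot2::theme_classic()
}
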
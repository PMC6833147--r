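#' Radar-style plot of a surplus table
#'
#' Relative surplus production capacities per condition on a polar layout,
#' the conventional way condition-specific precursor pools are compared:
#' each spoke is a biomass component, 100% the best condition for that
#' component.
#'
#' @param object a `surplus_table`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.surplus_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df <- df[!is.na(df$relative), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metabolite, y = .data$relative,
                                   group = .data$condition,
                                   colour = .data$condition,
                                   fill = .data$condition)) +
    ggplot2::geom_polygon(alpha = 0.15) +
    ggplot2::geom_point() +
    ggplot2::coord_polar() +
    ggplot2::ylim(0, 100) +
    ggplot2::labs(x = NULL, y = "relative surplus capacity (%)",
                  title = sprintf("Surplus production capacity at %.0f%% of maximal growth",
                                  100 * attr(object, "growth_fraction"))) +
    ggplot2::theme_minimal()
}

#' Predicted vs observed growth-rate scatter
#'
#' @param object a `rate_prediction` tibble.
#' @param ... unused.
#' @return A ggplot object annotated with the squared Pearson correlation.
#' @export
autoplot.rate_prediction <- function(object, ...) {
  rep_ <- correlation_report(object)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$observed_mu, y = .data$predicted_mu)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "observed growth rate (1/h)", y = "predicted growth rate (1/h)",
                  subtitle = sprintf("r^2 = %.4f (n = %d)",
                                     rep_$r_squared, rep_$n)) +
    ggplot2::theme_minimal()
}

#' Agreement tile plot for a sole-source phenotype screen
#'
#' @param object a `phenotype_screen` tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.phenotype_screen <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$role, y = .data$substrate,
                                       fill = .data$call)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$agreement), "",
                     ifelse(.data$agreement, "=", "x"))), size = 3) +
    ggplot2::labs(x = NULL, y = NULL, fill = "in silico call",
                  caption = "= agreement with observation, x disagreement") +
    ggplot2::theme_minimal()
}
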
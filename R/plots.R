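# ggplot2 visualizations of result objects.

#' Observed-versus-simulated scatter with outliers highlighted
#'
#' @param object An `mt_residuals` object.
#' @param label_outliers Label flagged categories?
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mt_residuals <- function(object, label_outliers = TRUE, ...) {
  d <- as_tibble(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$simulated,
                                       y = .data$observed)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey60", linewidth = 0.5) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$direction)) +
    ggplot2::scale_colour_manual(
      values = c(none = "black", positive = "red", negative = "blue")) +
    ggplot2::labs(x = "Simulated count (neutral reference)",
                  y = "Observed count",
                  colour = paste0("|std. residual| > ",
                                  attr(object, "threshold")))
  if (label_outliers && any(d$outlier)) {
    p <- p + ggplot2::geom_text(
      data = d[d$outlier, ],
      ggplot2::aes(label = .data$category),
      vjust = -0.6, size = 3)
  }
  p
}

#' Mutation-density bar chart
#'
#' @param object An `mt_density` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mt_density <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$group,
                                                     -.data$density),
                                  y = .data$density)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "Mutations per bp",
                  title = paste0("Mutation density by ",
                                 attr(object, "grouping")))
}

#' Substitution-spectrum bar chart
#'
#' @param object An `mt_spectrum` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mt_spectrum <- function(object, ...) {
  d <- as_tibble(object) %>%
    mutate(display = hl_label(.data$subst_type))
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$display,
                                                     -.data$freq),
                                  y = .data$freq)) +
    ggplot2::geom_col(fill = "darkred") +
    ggplot2::labs(x = NULL, y = "Relative frequency") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
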
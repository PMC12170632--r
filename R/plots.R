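#' Plot VAF against the number of synergies
#'
#' Global VAF curve with the selection threshold and, when [select_order()]
#' has been applied, the selected synergy number.
#'
#' @param object An `order_selection`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.order_selection <- function(object, ...) {
  df <- tidy(object)
  thr <- if (!is.null(object$thresholds)) object$thresholds[["global"]] else 0.90
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$global_vaf)) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = df$k) +
    ggplot2::labs(x = "Number of synergies", y = "Global VAF") +
    ggplot2::theme_minimal()
  if (!is.null(object$k_selected)) {
    p <- p + ggplot2::geom_vline(xintercept = object$k_selected,
                                 linetype = "dotted", colour = "steelblue")
  }
  p
}

#' Plot synergy weights and activation coefficients
#'
#' Weight vectors as per-synergy bar charts and coefficients as time curves
#' over the normalized movement cycle, faceted by synergy.
#'
#' @param object A `synergy_set`.
#' @param ... Unused.
#' @return A ggplot (weights and coefficients stacked via facetting).
#' @export
autoplot.synergy_set <- function(object, ...) {
  w <- tidy(object, matrix = "w")
  ggplot2::ggplot(w, ggplot2::aes(x = .data$muscle, y = .data$weight)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~synergy, ncol = 1) +
    ggplot2::labs(x = NULL, y = "Weight") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @rdname autoplot.synergy_set
#' @export
plot_coefficients <- function(object, ...) {
  cc <- tidy(object, matrix = "c")
  ggplot2::ggplot(cc, ggplot2::aes(x = .data$time, y = .data$coefficient,
                                   colour = .data$synergy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Movement cycle (%)", y = "Activation coefficient") +
    ggplot2::theme_minimal()
}
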
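#' Plot a coupling-function surface
#'
#' Renders a reconstructed coupling function over the
#' \eqn{2\pi \times 2\pi} phase grid as a filled raster, driver phase on
#' the x axis and target phase on the y axis.
#'
#' @param object A `coupling_grid` from [coupling_function_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coupling_grid <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$phi_from, .data$phi_to,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", name = "q (1/s)") +
    ggplot2::scale_x_continuous(
      breaks = c(0, pi, 2 * pi), labels = c("0", "π", "2π"),
      expand = c(0, 0)
    ) +
    ggplot2::scale_y_continuous(
      breaks = c(0, pi, 2 * pi), labels = c("0", "π", "2π"),
      expand = c(0, 0)
    ) +
    ggplot2::labs(
      x = bquote(phi[.(object$direction[1])]),
      y = bquote(phi[.(object$direction[2])]),
      title = sprintf("%s coupling %s → %s", object$component,
                      object$direction[1], object$direction[2])
    ) +
    ggplot2::theme_minimal()
}

#' Boxplots of coupling strengths by group
#'
#' The standard descriptive display for group contrasts: one box (median,
#' quartiles, whiskers to minimum/maximum) per group.
#'
#' @param data A data frame with a strength and a group column (e.g. the
#'   `summaries` tibble of [run_cohort()], filtered to one relationship).
#' @param value,group Column names (strings). Defaults `"net"`, `"group"`.
#' @return A ggplot object.
#' @export
plot_strengths <- function(data, value = "net", group = "group") {
  stopifnot(is.data.frame(data), value %in% names(data),
            group %in% names(data))
  ggplot2::ggplot(data, ggplot2::aes(.data[[group]], .data[[value]])) +
    ggplot2::geom_boxplot(coef = Inf, fill = "grey85") +
    ggplot2::labs(x = NULL, y = "coupling strength (1/s)") +
    ggplot2::theme_minimal()
}
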
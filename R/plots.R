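#' Plot a simulated trajectory
#'
#' Expression of all five genes over time, one line per gene.
#'
#' @param object a `clock_trajectory`.
#' @param window optional time window (length 2) to display.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.clock_trajectory <- function(object, window = NULL, ...) {
  df <- tidyr::pivot_longer(object, -"time_h", names_to = "gene",
                            values_to = "expression")
  if (!is.null(window))
    df <- df[df$time_h >= window[1] & df$time_h <= window[2], ]
  ggplot2::ggplot(df, ggplot2::aes(.data$time_h, .data$expression,
                                   colour = .data$gene)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "relative expression", colour = NULL)
}

#' Plot a parameter sweep
#'
#' Period versus parameter multiplier (log x-axis), coloured by sweep
#' direction; non-oscillating grid points are absent, so gaps mark
#' oscillation death.
#'
#' @param object a `clock_sweep`.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.clock_sweep <- function(object, ...) {
  df <- object[object$oscillating, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$multiplier, .data$period,
                                   colour = .data$direction)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = sprintf("%s (fraction of default)", object$param[1]),
                  y = "period (h)", colour = "sweep")
}

#' Plot per-edge importance
#'
#' ON-frequency of each regulation among oscillating configurations;
#' the dashed line marks the 0.5 frequency expected of a non-essential
#' edge.
#'
#' @param object an `edge_importance` table.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.edge_importance <- function(object, ...) {
  df <- object[order(object$on_frequency), ]
  df$label <- factor(df$label, levels = df$label)
  ggplot2::ggplot(df, ggplot2::aes(.data$on_frequency, .data$label,
                                   fill = .data$sign)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "frequency among oscillating configurations",
                  y = NULL, fill = NULL)
}

#' Plot a prototype trajectory
#' @param object a `prototype_trajectory`.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.prototype_trajectory <- function(object, ...) {
  df <- tidyr::pivot_longer(object, -"time", names_to = "stage",
                            values_to = "level")
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$level,
                                   colour = .data$stage)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "level", colour = NULL)
}
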
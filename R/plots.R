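# ggplot2 visualization methods for the main result types.

#' Plot a box-count log-log curve with its FD fit
#'
#' @param object an `fd_result`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.fd_result <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$log_size,
                                        y = .data$log_count)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "log box size (px)", y = "log box count",
      title = sprintf("Box-counting fit: FD = %.3f (r² = %.3f, qc = %s)",
                      object$fd, object$r_squared, object$qc)
    ) +
    ggplot2::theme_minimal()
  if (is.finite(object$fd)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$fitted),
                                color = "steelblue")
  }
  p
}

#' Plot per-slice FD values along the long axis
#'
#' @param object an `fd_stack`.
#' @param ... unused.
#' @return A ggplot of FD against the base-to-apex position, colored by qc.
#' @export
autoplot.fd_stack <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$fd,
                                       color = .data$qc)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(data = object[object$qc == "ok", ],
                       color = "grey40", linetype = 2) +
    ggplot2::labs(x = "long-axis position (0 = base, 1 = apex)",
                  y = "fractal dimension", color = "qc") +
    ggplot2::theme_minimal()
}

#' Plot a nine-slice FD profile
#'
#' @param object an `fd_profile`.
#' @param ... unused.
#' @return A ggplot of the interpolated template values.
#' @export
autoplot.fd_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$template_slice,
                                       y = .data$fd)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_continuous(breaks = 1:9) +
    ggplot2::labs(x = "template slice (1 = base, 9 = apex)",
                  y = "fractal dimension") +
    ggplot2::theme_minimal()
}

#' Plot the residual distribution with classification thresholds
#'
#' @param object a `trab_class` tibble.
#' @param ... unused.
#' @return A ggplot histogram of standardized residuals colored by class.
#' @export
autoplot.trab_class <- function(object, ...) {
  mode <- attr(object, "mode")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$residual,
                                            fill = .data$class)) +
    ggplot2::geom_histogram(bins = 60, alpha = 0.8) +
    ggplot2::labs(x = "standardized residual (s.d. units)", y = "count",
                  fill = "class",
                  title = paste("Trabeculation classes, mode =", mode)) +
    ggplot2::theme_minimal()
  if (mode != "deciles") {
    k <- c(sd_1 = 1, sd_1.5 = 1.5, sd_2 = 2)[[mode]]
    p <- p + ggplot2::geom_vline(xintercept = c(-k, k), linetype = 2)
  }
  p
}
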
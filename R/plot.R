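#' Plot a spectrum estimate
#'
#' Log-log scatter of the experimental PSD or AV values with one-standard-
#' deviation Gamma error bars (\eqn{y_k/\sqrt{\eta_k}}).
#'
#' @param object A `spectrum_estimate`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.spectrum_estimate <- function(object, ...) {
  kind <- spectrum_kind(object)
  df <- tibble::tibble(x = abscissa_of(object), value = object$value,
                       sd = object$value / sqrt(object$shape))
  labs <- if (kind == "psd") {
    list(x = "frequency (Hz)", y = expression(PSD ~ (nm^2 / Hz)))
  } else {
    list(x = expression(tau ~ (s)), y = expression(AV ~ (nm^2)))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$value)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(.data$value - .data$sd,
                                                    .Machine$double.xmin),
                                        ymax = .data$value + .data$sd),
                           width = 0, colour = "grey55") +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = labs$x, y = labs$y) +
    ggplot2::theme_minimal()
}

#' Plot a calibration fit with its data and residuals
#'
#' Upper panel: experimental values and fitted model curve on log-log
#' axes; lower panel: normalized residuals.
#'
#' @param object A `thermal_fit`.
#' @param ... Unused.
#' @return A ggplot object (two facets).
#' @exportS3Method ggplot2::autoplot
autoplot.thermal_fit <- function(object, ...) {
  df <- object$data
  long <- dplyr::bind_rows(
    tibble::tibble(x = df$abscissa, y = df$value, panel = "spectrum",
                   what = "data"),
    tibble::tibble(x = df$abscissa, y = df$fitted, panel = "spectrum",
                   what = "fit"),
    tibble::tibble(x = df$abscissa, y = df$residual, panel = "residuals",
                   what = "data")
  )
  xlab <- if (object$kind == "psd") "frequency (Hz)" else "tau (s)"
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(data = ~dplyr::filter(.x, .data$what == "data"),
                        size = 1) +
    ggplot2::geom_line(data = ~dplyr::filter(.x, .data$what == "fit"),
                       colour = "#d95f02") +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = xlab, y = NULL, title = object$model) +
    ggplot2::theme_minimal()
}

#' Residual plot of a calibration fit
#'
#' @param fit A `thermal_fit`.
#' @return A ggplot object: abscissa vs normalized residual.
#' @export
plot_residuals <- function(fit) {
  ggplot2::ggplot(fit$data,
                  ggplot2::aes(x = .data$abscissa, y = .data$residual)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = if (fit$kind == "psd") "frequency (Hz)" else "tau (s)",
                  y = expression(Delta[k])) +
    ggplot2::theme_minimal()
}
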
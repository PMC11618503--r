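#' Plot methods
#'
#' `autoplot()` methods for the main result types: the inherent-structure
#' vibrational density of states of a `mode_spectrum`, the linear shape fit,
#' the Gaussian-landscape fit, and a cooling curve.
#'
#' @param object The object to plot.
#' @param bin_width Histogram bin width in cm^-1 (spectra).
#' @param ... Unused.
#' @return A ggplot object.
#' @name pelwater-autoplot
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname pelwater-autoplot
#' @export
autoplot.mode_spectrum <- function(object, bin_width = 50, ...) {
  h <- vdos_histogram(object, bin_width = bin_width)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$omega_cm1, y = .data$density)) +
    ggplot2::geom_col(width = bin_width, fill = "steelblue") +
    ggplot2::labs(
      x = expression(omega ~ (cm^-1)), y = "IS-VDOS density",
      title = sprintf("%s IS-VDOS%s", object$kind,
                      if (object$kind == "ring-polymer")
                        sprintf(" (n_b = %d, T = %g K)", object$n_b,
                                object$temperature) else "")) +
    ggplot2::theme_minimal()
}

#' @rdname pelwater-autoplot
#' @export
autoplot.pel_shape_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$e_is, y = .data$S)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(intercept = object$a, slope = object$b,
                         colour = "firebrick") +
    ggplot2::labs(x = expression(e[IS] ~ (kJ/mol)), y = "shape function S",
                  subtitle = sprintf("S = %.4g + %.4g e_IS  (R^2 = %.4f)",
                                     object$a, object$b, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' @rdname pelwater-autoplot
#' @export
autoplot.pel_gaussian_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$e_is)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$E0, slope = -object$sigma2,
                         colour = "firebrick") +
    ggplot2::labs(x = expression(b(T) + 1 / (k[B] * T)),
                  y = expression(E[IS] ~ (kJ/mol)),
                  subtitle = sprintf("E0 = %.4g kJ/mol, sigma^2 = %.4g",
                                     object$E0, object$sigma2)) +
    ggplot2::theme_minimal()
}

#' @rdname pelwater-autoplot
#' @export
autoplot.cooling_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[c("temperature", "rho_g_cm3", "e_is_per_molecule",
                        "rg_O", "rg_H", "rg_is_O", "rg_is_H")],
    -"temperature", names_to = "quantity", values_to = "value")
  ggplot2::ggplot(dplyr::filter(long, !is.na(.data$value)),
                  ggplot2::aes(x = .data$temperature, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "T (K)", y = NULL, title = "isobaric cooling") +
    ggplot2::theme_minimal()
}
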
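# quick-look ggplot2 figures for the main result types

#' Plot methods
#'
#' `autoplot()` methods give quick-look figures: the ejection speed versus m
#' on log-log axes (read right to left to follow the time arrow), the
#' free-energy landscape over the ejection coordinate coloured by stage, and
#' the ensemble descent of m against time.
#'
#' @param object a `speed_profile`, `ejection_landscape` or
#'   `ejection_ensemble`.
#' @param ... unused.
#' @return a ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot speed_profile
#' @export
autoplot.speed_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$m, .data$V)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "m (monomers in cavity)",
                  y = expression(V[ej] ~ (sigma / t[u])))
}

#' @rdname autoplot.speed_profile
#' @method autoplot ejection_landscape
#' @export
autoplot.ejection_landscape <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$s, .data$F,
                                       colour = .data$stage)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "s (monomers in semi-space)",
                  y = expression(F / k[B] * T),
                  title = paste("regime", attr(object, "regime")))
}

#' @rdname autoplot.speed_profile
#' @method autoplot ejection_ensemble
#' @export
autoplot.ejection_ensemble <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$t, .data$m,
                                       group = .data$run)) +
    ggplot2::geom_step(alpha = 0.4) +
    ggplot2::labs(x = "t (t_u)", y = "m (monomers in cavity)")
}

#' @export
ggplot2::autoplot
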
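#' Plot a variant-density report
#'
#' @param object a [variant_density()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot density_report
#' @export
autoplot.density_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$var_class,
                                       y = .data$bp_per_variant)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "bp per variant") +
    ggplot2::theme_minimal()
}

#' Plot window-density tracks
#'
#' @param object a [window_density()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot window_density
#' @export
autoplot.window_density <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                               y = .data$density)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::labs(x = "position (Mb)", y = "covered fraction") +
    ggplot2::theme_minimal()
}
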
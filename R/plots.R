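# ggplot2 views of packings, traces and study results.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method ggplot2::autoplot
autoplot.mca_packing <- function(object, slice = "y", ...) {
  p <- object$particles
  mid <- stats::median(p[[slice]])
  keep <- abs(p[[slice]] - mid) < 0.4 * object$d
  ax <- setdiff(c("x", "y", "z"), slice)
  ggplot2::ggplot(p[keep, ],
                  ggplot2::aes(.data[[ax[1]]], .data[[ax[2]]],
                               colour = .data$region)) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "packing mid-slice", x = ax[1], y = ax[2])
}

#' @exportS3Method ggplot2::autoplot
autoplot.mca_result <- function(object, ...) {
  tr <- tidyr::pivot_longer(object$trace, -"t")
  ggplot2::ggplot(tr, ggplot2::aes(.data$t, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~name, scales = "free_y") +
    ggplot2::labs(x = "time [s]", y = NULL)
}

#' @exportS3Method ggplot2::autoplot
autoplot.stiffness_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$disp, .data$force)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "displacement [m]", y = "force [N]",
                  subtitle = paste("k =", format(object$stiffness,
                                                 digits = 4), "N/m"))
}

#' @exportS3Method ggplot2::autoplot
autoplot.convergence_study <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(.data$d * 1e3, .data$stiffness)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "element diameter [mm]", y = "stiffness [N/m]",
                  subtitle = paste0("scatter ",
                                    format(object$scatter, digits = 3), "%"))
}

#' @exportS3Method ggplot2::autoplot
autoplot.efd_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(object$summary,
                              dplyr::starts_with("frac_"),
                              names_prefix = "frac_")
  ggplot2::ggplot(long, ggplot2::aes(.data$PII / 1e3, .data$value,
                                     colour = .data$name)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$coverage, linetype = 2) +
    ggplot2::labs(x = "energy flux density [mJ/mm^2]",
                  y = paste("volume fraction of", object$focus),
                  colour = "criterion")
}
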
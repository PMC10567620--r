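#' Plot a sensitivity profile
#'
#' @param object A [sensitivity_profile()].
#' @param ... Unused.
#' @return A ggplot: sensitivity (cps/kBq) versus axial position.
#' @export
autoplot.sensitivity_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$slice_center, .data$sensitivity)) +
    ggplot2::geom_step(colour = "#2c7fb8") +
    ggplot2::labs(
      x = "axial position [cm]",
      y = "sensitivity [cps/kBq]"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pet_sim <- function(object, ...) {
  autoplot(object$profile) +
    ggplot2::ggtitle(object$design$name,
                     subtitle = sprintf("S_TB = %.1f cps/kBq, cut: %s",
                                        object$tb$S_TB, cut_label(object$cut)))
}

#' Overlay sensitivity profiles of several runs
#'
#' @param sims A list of `pet_sim` objects.
#' @return A ggplot with one profile per design.
#' @export
plot_profiles <- function(sims) {
  if (inherits(sims, "pet_sim")) sims <- list(sims)
  df <- purrr::map_dfr(sims, tidy)
  ggplot2::ggplot(df, ggplot2::aes(.data$slice_center, .data$sensitivity,
                                   colour = .data$design)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "axial position [cm]", y = "sensitivity [cps/kBq]",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Total sensitivity versus photosensor covered area
#'
#' Scatter of each design's total-body sensitivity against its photosensor
#' covered area, the cost-oriented comparison view.
#'
#' @param comparison Tibble from [compare_designs()].
#' @return A ggplot.
#' @export
plot_sensitivity_vs_area <- function(comparison) {
  ggplot2::ggplot(
    comparison,
    ggplot2::aes(.data$pm_covered_area_cm2, .data$S_TB,
                 shape = .data$family, colour = .data$material)
  ) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_x_continuous(labels = function(x) format(x, big.mark = ",")) +
    ggplot2::labs(
      x = expression("photosensor covered area" ~ (cm^2)),
      y = "total-body sensitivity [cps/kBq]"
    ) +
    ggplot2::theme_minimal()
}
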
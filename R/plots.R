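# ggplot2 display methods for the package's result types.

#' Plot an angle scan
#'
#' Reflectivity versus internal angle, optionally annotated with the
#' extracted TIR edge and SPR minimum.
#'
#' @param object An [angle_scan()].
#' @param features Optional one-row [scan_features()] tibble; when given,
#'   the two characteristic angles are drawn as vertical lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot angle_scan
#' @export
autoplot.angle_scan <- function(object, features = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$angle_deg,
                                    y = .data$reflectivity)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "internal angle (deg)", y = "reflectivity",
                  title = scan_metadata(object)$sample) +
    ggplot2::theme_minimal()
  if (!is.null(features)) {
    p <- p +
      ggplot2::geom_vline(xintercept = features$theta_tir,
                          linetype = "dashed", colour = "steelblue") +
      ggplot2::geom_vline(xintercept = features$theta_spr,
                          linetype = "dashed", colour = "firebrick")
  }
  p
}

#' Plot a density profile
#'
#' Species-resolved mass density versus distance from the wall.
#'
#' @param object A [density_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot density_profile
#' @export
autoplot.density_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$z_nm, y = .data$density_g_cm3,
                               colour = .data$species)) +
    ggplot2::geom_step(linewidth = 0.4) +
    ggplot2::labs(x = "distance from wall (nm)",
                  y = expression(density ~ (g ~ cm^-3))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
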
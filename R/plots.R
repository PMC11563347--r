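#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a radial intensity profile
#'
#' @param object A [radial_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot radial_profile
#' @export
autoplot.radial_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$radius * 1e6,
                                       y = .data$value / max(.data$value))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "radius (µm)", y = "relative intensity") +
    ggplot2::theme_minimal()
}

#' Plot a light-sheet thickness profile
#'
#' @param object A [sheet_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sheet_profile
#' @export
autoplot.sheet_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$z * 1e6, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "detection axis z (µm)", y = "relative intensity") +
    ggplot2::theme_minimal()
}

#' Plot a system axial PSF with its width conventions
#'
#' Marks the half-max and 1/e^2 levels whose crossings define the reported
#' widths.
#'
#' @param object A `system_psf`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot system_psf
#' @export
autoplot.system_psf <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$z * 1e6, y = .data$response)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = c(0.5, exp(-2)), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "detection axis z (µm)", y = "normalised response") +
    ggplot2::theme_minimal()
}

#' Plot the objective trace of a design fit
#'
#' @param object An `ssbb_design`.
#' @param ... Unused.
#' @return A ggplot of objective versus amplitude split.
#' @method autoplot ssbb_design
#' @export
autoplot.ssbb_design <- function(object, ...) {
  tr <- object$trace
  ggplot2::ggplot(tr[tr$stage == "coarse", ],
                  ggplot2::aes(x = .data$A1, y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = tr[tr$stage == "refined", ], colour = "red") +
    ggplot2::labs(x = expression(A[1]), y = "suppression objective") +
    ggplot2::theme_minimal()
}

#' Render a phase mask as a gray image
#'
#' @param mask A `phase_mask`.
#' @return A ggplot raster of the wrapped phase.
#' @export
plot_mask <- function(mask) {
  stopifnot(inherits(mask, "phase_mask"))
  df <- expand.grid(
    y = grid_axis(mask$grid$n_y, mask$grid$pitch) * 1e3,
    x = grid_axis(mask$grid$n_x, mask$grid$pitch) * 1e3
  )
  df$phase <- as.vector(mask$phase)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$phase)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 2 * pi)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = "phase (rad)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
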
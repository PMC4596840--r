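#' Plot an SSR calibration surface as a heat map
#'
#' @param object An `ssr_surface` from [grid_search()].
#' @param trans Transformation for the fill scale; default `"log10"`,
#'   which makes the basin around the optimum visible.
#' @param ... Unused.
#' @return A ggplot: SSR over the (w1, w2) grid, optimum marked with a
#'   cross.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.ssr_surface <- function(object, trans = "log10", ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$w1, y = .data$w2,
                                   fill = .data$ssr)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(trans = trans,
                                  name = expression(SSR ~ (deg^2))) +
    ggplot2::annotate("point", x = object$params$w1, y = object$params$w2,
                      shape = 4, size = 3, colour = "white") +
    ggplot2::labs(x = expression(W[1] ~ "(dimensionless)"),
                  y = expression(W[2] ~ (mu * m))) +
    ggplot2::theme_minimal()
}

#' Plot a modelled orientation field over the wing outline
#'
#' @param object An `orientation_field` from [field_on_grid()].
#' @param geom The [wing_geometry()] the field was evaluated on; drawn as
#'   margin (black) and ridge peaks (red).
#' @param arrow_um Arrow length in um; default 60% of the median nearest-
#'   neighbour spacing.
#' @param ... Unused.
#' @return A ggplot of unit orientation arrows.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.orientation_field <- function(object, geom = NULL,
                                       arrow_um = NULL, ...) {
  df <- object[!object$degenerate, ]
  if (is.null(arrow_um)) {
    ux <- sort(unique(df$x))
    arrow_um <- if (length(ux) > 1) 0.6 * min(diff(ux)) else 50
  }
  a <- df$phi_deg * pi / 180
  df$xend <- df$x + arrow_um * cos(a)
  df$yend <- df$y + arrow_um * sin(a)
  p <- ggplot2::ggplot(df)
  if (!is.null(geom)) {
    p <- p +
      ggplot2::geom_polygon(data = geom$margin,
                            ggplot2::aes(x = .data$x, y = .data$y),
                            fill = NA, colour = "black") +
      ggplot2::geom_path(data = geom$ridges,
                         ggplot2::aes(x = .data$x, y = .data$y,
                                      group = .data$ridge),
                         colour = "red")
  }
  p +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      arrow = ggplot2::arrow(length = ggplot2::unit(1.2, "mm")),
      colour = "steelblue") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = expression(x ~ (mu * m)), y = expression(y ~ (mu * m))) +
    ggplot2::theme_minimal()
}

#' Predicted-versus-observed orientation scatter
#'
#' @param predicted,observed Data frames with `quadrat`, `phi_deg` over
#'   the same quadrats (degrees; plotted on the branch centred at 180).
#' @return A ggplot with the one-to-one line dotted.
#' @export
plot_fidelity <- function(predicted, observed) {
  m <- dplyr::inner_join(as_tibble(predicted), as_tibble(observed),
                         by = "quadrat", suffix = c("_pred", "_obs"))
  m$phi_pred <- unwrap_to_branch(m$phi_deg_pred)
  m$phi_obs <- unwrap_to_branch(m$phi_deg_obs)
  ggplot2::ggplot(m, ggplot2::aes(x = .data$phi_obs, y = .data$phi_pred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(observed ~ phi ~ (degree)),
                  y = expression(predicted ~ phi ~ (degree))) +
    ggplot2::theme_minimal()
}
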
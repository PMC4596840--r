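#' Orientation-model parameters
#'
#' The model combines three antiwetting strategies with two tunable weights:
#' `w1` (dimensionless) scales the upslope term and `w2` (um) scales the
#' edge-attraction term; the distal unit vector carries an implicit weight
#' of 1 and sets the overall scale of the other two.
#'
#' @param w1 Non-negative dimensionless weight of the upslope term.
#' @param w2 Non-negative weight of the nearest-edge term, in micrometres
#'   (it divides one power of the distance to the edge, making the term
#'   dimensionless).
#' @param distal Fixed distal unit vector; default `c(-1, 0)` (positive X
#'   points proximally).
#' @return An object of class `model_params`.
#' @examples
#' model_params(0.544, 196)
#' @export
model_params <- function(w1, w2, distal = c(-1, 0)) {
  if (!is.numeric(w1) || length(w1) != 1L || !is.finite(w1) || w1 < 0) {
    abort("`w1` must be a single finite non-negative number.")
  }
  if (!is.numeric(w2) || length(w2) != 1L || !is.finite(w2) || w2 < 0) {
    abort("`w2` must be a single finite non-negative number (um).")
  }
  nb <- sqrt(sum(distal^2))
  if (length(distal) != 2L || !all(is.finite(distal)) || nb == 0) {
    abort("`distal` must be a finite non-zero 2-vector.")
  }
  structure(list(w1 = w1, w2 = w2, distal = distal / nb),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<model_params> w1 = %g, w2 = %g um, distal = (%g, %g)\n",
              x$w1, x$w2, x$distal[1], x$distal[2]))
  invisible(x)
}

#' Combined (unnormalized) orientation vector
#'
#' Evaluates the three-term sum
#' `C = w1 * u + w2 * D / ||D||^2 + B`
#' where `u` is the local upslope unit vector (toward the nearest ridge
#' peak; zero on a peak), `D` the displacement to the nearest wing edge
#' (norm clamped at 0.37 um so the term stays finite on the margin), and
#' `B` the fixed distal unit vector.
#'
#' @param points Data frame with columns `x`, `y` (um).
#' @param params A [model_params()].
#' @param geom A [wing_geometry()].
#' @return A tibble with columns `cx`, `cy` per point.
#' @export
combined_vector <- function(points, params, geom) {
  stopifnot(inherits(params, "model_params"),
            inherits(geom, "wing_geometry"))
  points <- as_tibble(points)
  u <- upslope_direction(points, geom)
  D <- edge_displacement(points, geom)
  dn2 <- pmax(D$dx^2 + D$dy^2, DEGENERATE_NORM_TOL^2)
  tibble(
    cx = params$w1 * u$ux + params$w2 * D$dx / dn2 + params$distal[1],
    cy = params$w1 * u$uy + params$w2 * D$dy / dn2 + params$distal[2]
  )
}

#' Modelled microtrichial orientation at given points
#'
#' Normalizes the combined vector to a unit direction and reports its angle
#' `phi` in degrees, measured counter-clockwise from the positive X axis
#' (proximal), in `[0, 360)`. Exact cancellation of the three terms
#' (`||C|| <= 1e-12`) has no meaningful orientation: it is flagged, and an
#' error is raised unless `degenerate = "flag"`.
#'
#' @inheritParams combined_vector
#' @param degenerate `"error"` (default) aborts on a degenerate point;
#'   `"flag"` returns it with `phi_deg = NA` and `degenerate = TRUE`.
#' @return A tibble with columns `x`, `y`, `phi_deg`, `degenerate`.
#' @examples
#' geom <- wing_geometry(
#'   margin = data.frame(x = c(0, 1000, 1000, 0), y = c(0, 0, 400, 400)),
#'   ridges = data.frame(ridge = 1, x = c(100, 900), y = c(200, 200))
#' )
#' model_orientation(data.frame(x = 500, y = 100),
#'                   model_params(0.544, 196), geom)
#' @export
model_orientation <- function(points, params, geom,
                              degenerate = c("error", "flag")) {
  degenerate <- match.arg(degenerate)
  points <- as_tibble(points)
  cc <- combined_vector(points, params, geom)
  nrm <- sqrt(cc$cx^2 + cc$cy^2)
  bad <- nrm <= DEGENERATE_NORM_TOL
  if (any(bad) && degenerate == "error") {
    abort(sprintf(
      "degenerate orientation (||C|| <= %g) at point(s) %s: the model terms cancel exactly.",
      DEGENERATE_NORM_TOL, paste(which(bad), collapse = ", ")))
  }
  phi <- wrap_angle(atan2(cc$cy, cc$cx) * 180 / pi)
  phi[bad] <- NA_real_
  tibble(x = points$x, y = points$y, phi_deg = phi, degenerate = bad)
}

#' Wrap angles to [0, 360)
#'
#' @param phi_deg Angles in degrees.
#' @return Angles in `[0, 360)`.
#' @export
wrap_angle <- function(phi_deg) {
  out <- phi_deg %% 360
  out[out == 360] <- 0
  out
}

#' Evaluate the orientation field on a regular grid
#'
#' Lays a square grid of the given spacing over the margin's bounding box
#' and evaluates the modelled orientation at every grid point strictly
#' inside the wing. Degenerate points (exactly cancelling terms) are kept
#' and flagged rather than dropped.
#'
#' @param geom A [wing_geometry()].
#' @param params A [model_params()].
#' @param spacing Grid spacing in um; default 100.
#' @return A tibble of class `orientation_field` with columns `x`, `y`,
#'   `phi_deg`, `degenerate`.
#' @export
field_on_grid <- function(geom, params, spacing = 100) {
  stopifnot(inherits(geom, "wing_geometry"))
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0) {
    abort("`spacing` must be a single positive number (um).")
  }
  gx <- seq(min(geom$margin$x), max(geom$margin$x), by = spacing)
  gy <- seq(min(geom$margin$y), max(geom$margin$y), by = spacing)
  pts <- tidyr::expand_grid(x = gx, y = gy)
  pts <- pts[point_in_wing(pts, geom), ]
  out <- model_orientation(pts, params, geom, degenerate = "flag")
  if (any(out$degenerate)) {
    warn(sprintf("%d grid point(s) have a degenerate orientation.",
                 sum(out$degenerate)))
  }
  class(out) <- c("orientation_field", class(out))
  out
}
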
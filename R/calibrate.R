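#' Wrapped absolute angular residual
#'
#' The absolute difference between two orientations, wrapped to
#' `[0, 180]` degrees, i.e. the unsigned angle between the two direction
#' vectors. This is the residual entering the sum-of-squares calibration
#' objective.
#'
#' @param phi_a,phi_b Orientations in degrees (any branch; vectorized).
#' @return Residuals in degrees, in `[0, 180]`.
#' @examples
#' angular_residual(30, 50)     # 20
#' angular_residual(179, -179)  # 2
#' @export
angular_residual <- function(phi_a, phi_b) {
  d <- (phi_a - phi_b) %% 360
  pmin(d, 360 - d)
}

#' Sum of squared angular residuals (SSR)
#'
#' The calibration objective: the modelled orientation is evaluated at each
#' in-wing quadrat centre and compared against the observed mean
#' orientation of the hairs in that quadrat; squared wrapped residuals are
#' summed. Quadrats whose centre lies outside the wing are excluded (the
#' model would be predicting orientations off the wing surface).
#'
#' @param params A [model_params()].
#' @param quadrats A quadrat tibble as returned by [quadrat_samples()] or
#'   [sample_quadrats()]: columns `quadrat`, `x`, `y`, `mean_phi_deg`,
#'   `in_wing`.
#' @param geom A [wing_geometry()].
#' @return SSR in degrees squared (a single number).
#' @export
ssr <- function(params, quadrats, geom) {
  q <- quadrats[quadrats$in_wing, ]
  if (nrow(q) == 0L) abort("no in-wing quadrats.")
  pred <- model_orientation(q[c("x", "y")], params, geom,
                            degenerate = "flag")
  if (any(pred$degenerate)) {
    abort(sprintf("degenerate model orientation at quadrat(s): %s",
                  paste(q$quadrat[pred$degenerate], collapse = ", ")))
  }
  sum(angular_residual(pred$phi_deg, q$mean_phi_deg)^2)
}

#' Brute-force grid search for the model weights
#'
#' Evaluates the SSR objective on the full cartesian grid of `w1` and `w2`
#' values and reports the minimizing pair. The upslope and edge vectors at
#' each quadrat centre do not depend on the weights, so they are computed
#' once and the whole surface is filled by vectorized arithmetic; the
#' result is identical to looping [ssr()] over the grid. Ties for the
#' minimum (possible on flat plateaus) are broken toward the smallest `w1`,
#' then the smallest `w2`, with a warning. Grid cells where the model terms
#' cancel exactly at some quadrat get `NA` and are excluded from the
#' argmin.
#'
#' @inheritParams ssr
#' @param w1 Increasing vector of dimensionless upslope weights to test.
#' @param w2 Increasing vector of edge weights (um) to test.
#' @param distal Distal unit vector; default `c(-1, 0)`.
#' @return An object of class `ssr_surface`: a list with the grids, the SSR
#'   matrix (`w1` by `w2`, degrees squared), the best-fit `params`, and the
#'   minimum SSR. Methods: [tidy()], [glance()], [autoplot()].
#' @examples
#' # see the package vignette for a full synthetic calibration
#' @export
grid_search <- function(quadrats, geom, w1, w2, distal = c(-1, 0)) {
  stopifnot(inherits(geom, "wing_geometry"))
  if (length(w1) < 1L || is.unsorted(w1, strictly = TRUE)) {
    abort("`w1` must be a non-empty strictly increasing vector.")
  }
  if (length(w2) < 1L || is.unsorted(w2, strictly = TRUE)) {
    abort("`w2` must be a non-empty strictly increasing vector.")
  }
  if (any(w1 < 0) || any(w2 < 0)) abort("weights must be non-negative.")
  q <- quadrats[quadrats$in_wing, ]
  if (nrow(q) == 0L) abort("no in-wing quadrats.")
  nb <- sqrt(sum(distal^2))
  bx <- distal[1] / nb; by <- distal[2] / nb

  u <- upslope_direction(q[c("x", "y")], geom)
  D <- edge_displacement(q[c("x", "y")], geom)
  dn2 <- pmax(D$dx^2 + D$dy^2, DEGENERATE_NORM_TOL^2)
  ex <- D$dx / dn2; ey <- D$dy / dn2
  obs <- q$mean_phi_deg * pi / 180
  ox <- cos(obs); oy <- sin(obs)

  n1 <- length(w1); n2 <- length(w2)
  ssr_mat <- matrix(0, n1, n2)
  ones1 <- rep(1, n1); ones2 <- rep(1, n2)
  for (k in seq_len(nrow(q))) {
    cx <- outer(w1 * u$ux[k], ones2) + outer(ones1, w2 * ex[k]) + bx
    cy <- outer(w1 * u$uy[k], ones2) + outer(ones1, w2 * ey[k]) + by
    nrm2 <- cx^2 + cy^2
    # unsigned angle between model vector and observed direction, [0, 180]
    resid <- atan2(abs(cx * oy[k] - cy * ox[k]),
                   cx * ox[k] + cy * oy[k]) * 180 / pi
    resid[nrm2 <= DEGENERATE_NORM_TOL^2] <- NA_real_
    ssr_mat <- ssr_mat + resid^2
  }

  if (all(is.na(ssr_mat))) abort("SSR is degenerate on the whole grid.")
  mn <- min(ssr_mat, na.rm = TRUE)
  hits <- which(ssr_mat == mn, arr.ind = TRUE)
  if (nrow(hits) > 1L) {
    warn(sprintf("%d grid cells tie for the minimum SSR; reporting the smallest (w1, w2).",
                 nrow(hits)))
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  }
  i <- hits[1, 1]; j <- hits[1, 2]

  structure(
    list(
      w1 = w1, w2 = w2, ssr = ssr_mat,
      params = model_params(w1[i], w2[j], distal = c(bx, by)),
      min_ssr = mn, n_quadrats = nrow(q),
      n_degenerate = sum(is.na(ssr_mat))
    ),
    class = "ssr_surface"
  )
}

#' @export
print.ssr_surface <- function(x, ...) {
  cat(sprintf(
    "<ssr_surface> %d x %d grid, %d quadrats\n  optimum: w1 = %g, w2 = %g um, SSR = %.4g deg^2\n",
    length(x$w1), length(x$w2), x$n_quadrats,
    x$params$w1, x$params$w2, x$min_ssr))
  invisible(x)
}

#' @describeIn grid_search The SSR surface as a long tibble
#'   (`w1`, `w2`, `ssr`).
#' @param x An `ssr_surface`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
#' @export
tidy.ssr_surface <- function(x, ...) {
  tidyr::expand_grid(w1 = x$w1, w2 = x$w2) |>
    dplyr::mutate(ssr = as.vector(t(x$ssr)))
}

#' @describeIn grid_search One-row summary of the fit: the optimum, its
#'   SSR, the RMS residual and the grid dimensions.
#' @exportS3Method generics::glance
#' @export
glance.ssr_surface <- function(x, ...) {
  tibble(
    w1 = x$params$w1, w2 = x$params$w2, min_ssr = x$min_ssr,
    rms_residual = sqrt(x$min_ssr / x$n_quadrats),
    n_quadrats = x$n_quadrats,
    n_w1 = length(x$w1), n_w2 = length(x$w2),
    n_degenerate = x$n_degenerate
  )
}
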
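#' Wrap-aware arithmetic mean orientation
#'
#' The arithmetic mean of a set of orientation angles, taken on the
#' continuous 360-degree branch centred on the resultant-vector (circular
#' mean) direction, so the wrap-around cannot corrupt it: `c(350, 10)`
#' averages to 0, not 180. Whenever all angles lie within a 180-degree arc
#' — true of distally biased hair samples, which cluster around 180
#' degrees — the branch contains the whole sample and the result is
#' exactly the plain arithmetic mean of the angles on that arc. The only
#' undefined input is a sample whose direction vectors cancel exactly
#' (zero resultant), where no branch centre exists.
#'
#' @param angles Orientations in degrees (at least one).
#' @return The mean orientation in degrees, in `[0, 360)`.
#' @examples
#' mean_orientation(c(170, 190))  # 180
#' mean_orientation(c(350, 10))   # 0
#' @export
mean_orientation <- function(angles) {
  if (length(angles) == 0L) abort("`angles` must contain at least one angle.")
  if (!all(is.finite(angles))) abort("`angles` must be finite.")
  a <- angles * pi / 180
  sx <- mean(cos(a)); sy <- mean(sin(a))
  if (sqrt(sx^2 + sy^2) <= DEGENERATE_NORM_TOL) {
    abort("mean orientation undefined: angles cancel (zero resultant).")
  }
  centre <- wrap_angle(atan2(sy, sx) * 180 / pi)
  wrap_angle(mean(unwrap_to_branch(wrap_angle(angles), centre)))
}

#' Assemble quadrat samples from centres and per-hair orientations
#'
#' Joins quadrat centre locations with the hair orientations measured in
#' each quadrat, computes the per-quadrat mean orientation, and flags
#' whether each centre lies inside the wing margin. This is the canonical
#' per-quadrat table consumed by [ssr()], [grid_search()] and the
#' directional-bias statistics.
#'
#' @param centres Data frame with columns `quadrat`, `x`, `y` (um).
#' @param orientations Data frame with columns `quadrat`, `phi_deg`: one
#'   row per hair. Every `quadrat` id must appear in `centres`.
#' @param geom A [wing_geometry()]; used for the in-wing flag.
#' @return A tibble with one row per quadrat: `quadrat`, `x`, `y`,
#'   `angles` (list-column of hair angles, degrees), `n_hairs`,
#'   `mean_phi_deg`, `in_wing`.
#' @export
quadrat_samples <- function(centres, orientations, geom) {
  centres <- as_tibble(centres)
  orientations <- as_tibble(orientations)
  if (!all(c("quadrat", "x", "y") %in% names(centres))) {
    abort("`centres` must have columns `quadrat`, `x`, `y`.")
  }
  if (!all(c("quadrat", "phi_deg") %in% names(orientations))) {
    abort("`orientations` must have columns `quadrat`, `phi_deg`.")
  }
  if (anyDuplicated(centres$quadrat)) {
    abort("duplicate quadrat ids in `centres`.")
  }
  missing_ids <- setdiff(unique(orientations$quadrat), centres$quadrat)
  if (length(missing_ids)) {
    abort(paste0("orientation rows reference unknown quadrat id(s): ",
                 paste(missing_ids, collapse = ", ")))
  }
  if (!all(is.finite(orientations$phi_deg))) {
    abort("`orientations$phi_deg` must be finite angles in degrees.")
  }

  ang <- orientations |>
    dplyr::group_by(.data$quadrat) |>
    dplyr::summarise(angles = list(wrap_angle(.data$phi_deg)),
                     .groups = "drop")
  out <- dplyr::left_join(centres, ang, by = "quadrat")
  out$angles <- purrr::map(out$angles, function(a) a %||% double())
  out |>
    dplyr::mutate(
      n_hairs = purrr::map_int(.data$angles, length),
      mean_phi_deg = purrr::map_dbl(
        .data$angles,
        function(a) if (length(a)) mean_orientation(a) else NA_real_),
      in_wing = point_in_wing(dplyr::pick("x", "y"), geom)
    )
}

#' Directional-bias classification of quadrats and hairs
#'
#' A quadrat's mean orientation is called *upslope-biased* when its
#' direction vector has a strictly positive dot product with the local
#' upslope unit vector, *edgeward-biased* when strictly positive against
#' the direction to the nearest edge, and an individual hair is
#' *distal-biased* when strictly positive against the distal unit vector
#' `(-1, 0)` (equivalently, `cos(phi) < 0`). An orientation exactly
#' perpendicular to the reference direction counts as not biased; dot
#' products within 1e-12 of zero are treated as exact perpendiculars so
#' floating-point noise (e.g. `sin(pi)` not being 0) cannot flip the rule.
#'
#' `classify_upslope()` is undefined (returns `NA`) for a quadrat whose
#' centre sits on a ridge peak, where the upslope direction vanishes.
#'
#' @param quadrats A quadrat tibble (see [quadrat_samples()]).
#' @param geom A [wing_geometry()].
#' @return The input tibble with a logical column appended (`upslope` or
#'   `edgeward`).
#' @export
classify_upslope <- function(quadrats, geom) {
  u <- upslope_direction(quadrats[c("x", "y")], geom)
  a <- quadrats$mean_phi_deg * pi / 180
  dp <- cos(a) * u$ux + sin(a) * u$uy
  dplyr::mutate(quadrats,
                upslope = dplyr::if_else(u$on_ridge, NA,
                                         dp > DEGENERATE_NORM_TOL))
}

#' @rdname classify_upslope
#' @export
classify_edgeward <- function(quadrats, geom) {
  D <- edge_displacement(quadrats[c("x", "y")], geom)
  dn <- sqrt(D$dx^2 + D$dy^2)
  a <- quadrats$mean_phi_deg * pi / 180
  dp <- (cos(a) * D$dx + sin(a) * D$dy) / dn
  dplyr::mutate(quadrats, edgeward = dp > DEGENERATE_NORM_TOL)
}

#' @rdname classify_upslope
#' @param phi_deg Hair orientations in degrees (vectorized).
#' @param distal Distal unit vector; default `c(-1, 0)`.
#' @return `classify_distal()`: a logical vector.
#' @export
classify_distal <- function(phi_deg, distal = c(-1, 0)) {
  nb <- sqrt(sum(distal^2))
  a <- phi_deg * pi / 180
  (cos(a) * distal[1] + sin(a) * distal[2]) / nb > DEGENERATE_NORM_TOL
}

#' Exact upper binomial tail under a fair coin
#'
#' `P(X >= k)` for `X ~ Binomial(n, 1/2)`, by exact summation of binomial
#' coefficients (all integers involved are below 2^53 for the `n` used
#' here, so the sum is exact in double precision). Used for the sign-test
#' style question: how often would at least `k` of `n` quadrats show a
#' directional bias if orientations were random?
#'
#' @param k,n Counts, `0 <= k <= n`.
#' @return The tail probability, a single number in `[0, 1]`.
#' @examples
#' binomial_tail(16, 24)  # ~ 0.076, prints as 8%
#' binomial_tail(18, 23)  # ~ 0.0053, prints as 0.5%
#' @export
binomial_tail <- function(k, n) {
  if (length(k) != 1L || length(n) != 1L || k != round(k) || n != round(n) ||
      k < 0 || n < 1 || k > n) {
    abort("`k` and `n` must be single integers with 0 <= k <= n.")
  }
  sum(choose(n, seq.int(k, n))) / 2^n
}

#' Summarize a directional-bias count
#'
#' @param n_biased Number of units (quadrats, hairs) showing the bias.
#' @param n_total Total number of units.
#' @return A one-row tibble: `n_biased`, `n_total`, `fraction`,
#'   `tail_probability` (exact `P(X >= n_biased)` under a fair coin).
#' @export
bias_summary <- function(n_biased, n_total) {
  tibble(
    n_biased = as.integer(n_biased), n_total = as.integer(n_total),
    fraction = n_biased / n_total,
    tail_probability = binomial_tail(n_biased, n_total)
  )
}

#' Residual to nearest-edge direction versus distance to the edge
#'
#' Ordinary least-squares fit of the absolute angular residual between each
#' quadrat's observed mean orientation and the direction to its nearest
#' edge, against the quadrat's distance to that edge. A positive slope says
#' hairs align with the edge direction more closely the nearer the edge —
#' the signature of an edge-attraction term whose influence decays with
#' distance. Only in-wing quadrats enter.
#'
#' @param quadrats A quadrat tibble (see [quadrat_samples()]).
#' @param geom A [wing_geometry()].
#' @return A one-row tibble: `r` (Pearson correlation), `p_value`
#'   (two-sided t test on the correlation, n - 2 df), `r_squared`, `slope`
#'   (deg/um), `intercept` (deg), `n`.
#' @export
residual_distance_fit <- function(quadrats, geom) {
  q <- quadrats[quadrats$in_wing, ]
  if (nrow(q) < 3L) abort("need at least 3 in-wing quadrats.")
  D <- edge_displacement(q[c("x", "y")], geom)
  edge_phi <- wrap_angle(atan2(D$dy, D$dx) * 180 / pi)
  y <- angular_residual(edge_phi, q$mean_phi_deg)
  x <- D$dist
  if (stats::var(x) == 0) abort("zero variance in distance to the edge.")
  fit <- lm(y ~ x)
  ct <- cor.test(x, y)
  tibble(
    r = unname(ct$estimate), p_value = ct$p.value,
    r_squared = unname(ct$estimate)^2,
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    n = nrow(q)
  )
}

#' Model fidelity: predicted versus observed quadrat orientations
#'
#' Compares modelled and observed mean orientations over a common set of
#' quadrats. The coefficient of determination is computed on angles
#' unwrapped to the continuous branch centred on 180 degrees (the distal
#' direction, where the observations cluster), so that the wrap-around
#' does not manufacture spurious variance; the residual summary uses the
#' wrapped angular residual, which needs no branch choice.
#'
#' @param predicted,observed Data frames with columns `quadrat`,
#'   `phi_deg`, covering the same quadrat set.
#' @param residual_threshold Residuals strictly below this (degrees) count
#'   toward `frac_below`; default 25.
#' @return A one-row tibble: `r_squared`, `p_value` (two-sided correlation
#'   test, n - 2 df), `median_residual`, `max_residual`, `q1_residual`,
#'   `q3_residual` (degrees), `frac_below`, `n`.
#' @export
model_fidelity <- function(predicted, observed, residual_threshold = 25) {
  predicted <- as_tibble(predicted)
  observed <- as_tibble(observed)
  if (!setequal(predicted$quadrat, observed$quadrat) ||
      anyDuplicated(predicted$quadrat) || anyDuplicated(observed$quadrat)) {
    abort("`predicted` and `observed` must cover the same quadrats exactly once.")
  }
  m <- dplyr::inner_join(predicted, observed, by = "quadrat",
                         suffix = c("_pred", "_obs"))
  # branch centred on 180: angles as-is in [0, 360)
  xp <- unwrap_to_branch(m$phi_deg_pred, centre = 180)
  xo <- unwrap_to_branch(m$phi_deg_obs, centre = 180)
  res <- angular_residual(m$phi_deg_pred, m$phi_deg_obs)
  qs <- stats::quantile(res, c(0.25, 0.5, 0.75), names = FALSE)
  if (nrow(m) < 3L || stats::var(xo) == 0 || stats::var(xp) == 0) {
    r2 <- if (all(res == 0)) 1 else NA_real_
    pv <- NA_real_
  } else {
    ct <- cor.test(xp, xo)
    r2 <- unname(ct$estimate)^2
    pv <- ct$p.value
  }
  tibble(
    r_squared = r2, p_value = pv,
    median_residual = qs[2], max_residual = max(res),
    q1_residual = qs[1], q3_residual = qs[3],
    frac_below = mean(res < residual_threshold),
    n = nrow(m)
  )
}

# Map angles (degrees) onto the continuous branch (centre-180, centre+180].
unwrap_to_branch <- function(phi_deg, centre = 180) {
  d <- (phi_deg - centre) %% 360
  d[d > 180] <- d[d > 180] - 360
  centre + d
}
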
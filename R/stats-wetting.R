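#' Censor a rolloff-angle trial
#'
#' In the tilting assay the stage is raised in 1-degree steps up to 10
#' degrees; if the drop's contact line has not advanced by then, the trial
#' is right-censored and recorded as 11 degrees. Observed rolloff angles
#' must lie in `(0, 10]`.
#'
#' @param raw_angle Observed rolloff angle in degrees, or `NA` when no
#'   rolloff occurred by the 10-degree mark (vectorized).
#' @return A tibble with columns `angle` (degrees, censored trials carry
#'   11) and `censored` (logical).
#' @examples
#' censor_rolloff(c(7, NA, 3))
#' @export
censor_rolloff <- function(raw_angle) {
  cens <- is.na(raw_angle)
  obs <- raw_angle[!cens]
  if (any(obs <= 0 | obs > 10)) {
    abort("observed rolloff angles must lie in (0, 10] degrees; use NA for trials with no rolloff.")
  }
  angle <- raw_angle
  angle[cens] <- 11
  tibble(angle = angle, censored = cens)
}

#' Inverse-SEM weighted mean of per-wing rolloff angles
#'
#' Pools per-wing mean rolloff angles into a single direction-level value,
#' weighting each wing by the reciprocal of the standard error of its mean
#' (precise wings count more). The reported dispersion is the first-order
#' error-propagated standard deviation of the weighted mean,
#' `sqrt(sum(w_i^2 s_i^2)) / sum(w_i)` with `w_i = 1/s_i`, which for these
#' weights reduces to `sqrt(n) / sum(1/s_i)`.
#'
#' @param means Per-wing mean rolloff angles (degrees).
#' @param sems Per-wing standard errors of those means (degrees, all > 0).
#' @return A one-row tibble: `mean`, `dispersion` (degrees), `n_wings`.
#' @examples
#' weighted_rolloff_mean(c(4, 8), c(0.5, 1))  # mean 16/3
#' @export
weighted_rolloff_mean <- function(means, sems) {
  if (length(means) == 0L || length(means) != length(sems)) {
    abort("`means` and `sems` must be non-empty and the same length.")
  }
  if (any(!is.finite(sems)) || any(sems <= 0)) {
    abort("all `sems` must be positive.")
  }
  w <- 1 / sems
  tibble(
    mean = sum(w * means) / sum(w),
    dispersion = sqrt(sum(w^2 * sems^2)) / sum(w),
    n_wings = length(means)
  )
}

#' Force-of-retention ratio
#'
#' `R_FR = sin(beta_p) / sin(beta_d)`: the ratio of the drop-retaining
#' force in the proximal versus distal tilting directions, computed from
#' the respective rolloff angles. A value above 1 means drops shed more
#' easily toward the wing tip than toward the body.
#'
#' @param beta_p,beta_d Rolloff angles (degrees) in the proximal and
#'   distal directions; must lie strictly between 0 and 90.
#' @return The dimensionless ratio.
#' @examples
#' retention_ratio(8.5, 5.8)  # ~ 1.46
#' @export
retention_ratio <- function(beta_p, beta_d) {
  if (length(beta_p) != 1L || length(beta_d) != 1L ||
      !is.finite(beta_p) || !is.finite(beta_d) ||
      beta_p <= 0 || beta_p >= 90 || beta_d <= 0 || beta_d >= 90) {
    abort("rolloff angles must lie strictly between 0 and 90 degrees.")
  }
  sin(beta_p * pi / 180) / sin(beta_d * pi / 180)
}

#' Reduce a trial-level rolloff assay to the retention ratio
#'
#' Takes trial-level rolloff measurements, forms per-wing means and SEMs
#' in each tilting direction, pools wings by the inverse-SEM weighted
#' mean, and evaluates the force-of-retention ratio from the two pooled
#' angles.
#'
#' @param trials Data frame with columns `wing`, `direction` (`"proximal"`
#'   or `"distal"`), `angle` (degrees, censored trials already at 11) and
#'   optionally `censored` (logical).
#' @param include_censored Keep censored (11-degree) trials in per-wing
#'   means? Default `TRUE`, matching the assay protocol; set `FALSE` as a
#'   sensitivity check.
#' @return A list with `per_direction` (tibble: `direction`, `mean`,
#'   `dispersion`, `n_wings`, `n_trials`) and `retention_ratio`.
#' @export
wetting_summary <- function(trials, include_censored = TRUE) {
  trials <- as_tibble(trials)
  req <- c("wing", "direction", "angle")
  if (!all(req %in% names(trials))) {
    abort("`trials` must have columns `wing`, `direction`, `angle`.")
  }
  if (!all(trials$direction %in% c("proximal", "distal"))) {
    abort('`direction` must be "proximal" or "distal".')
  }
  if (!include_censored && "censored" %in% names(trials)) {
    trials <- trials[!trials$censored, ]
  }
  per_wing <- trials |>
    dplyr::group_by(.data$direction, .data$wing) |>
    dplyr::summarise(
      m = mean(.data$angle),
      s = stats::sd(.data$angle) / sqrt(dplyr::n()),
      k = dplyr::n(), .groups = "drop")
  if (any(!is.finite(per_wing$s) | per_wing$s <= 0)) {
    abort("every wing needs >= 2 trials with non-identical angles (positive SEM).")
  }
  per_direction <- per_wing |>
    dplyr::group_by(.data$direction) |>
    dplyr::reframe(weighted_rolloff_mean(.data$m, .data$s),
                   n_trials = sum(.data$k))
  get_dir <- function(d) per_direction$mean[per_direction$direction == d]
  bp <- get_dir("proximal"); bd <- get_dir("distal")
  if (!length(bp) || !length(bd)) {
    abort("`trials` must contain both proximal and distal directions.")
  }
  list(per_direction = per_direction,
       retention_ratio = retention_ratio(bp, bd))
}
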
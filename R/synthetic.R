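#' Configuration for the synthetic wing generator
#'
#' Defaults emulate the digitized specimen the model was developed on: an
#' elongated wing a few millimetres long with a handful of roughly
#' spanwise ridge-peak lines, 24 quadrats of 56 um side sampled at random
#' over the wing's bounding box, about 20 measurable hairs per quadrat,
#' and ground-truth weights `w1 = 0.544`, `w2 = 196` um.
#'
#' @param seed Integer seed; every generated quantity is reproducible
#'   from it.
#' @param length_um,chord_um Wing length (span direction, along X) and
#'   maximum chord (along Y), in um.
#' @param n_ridges Number of ridge-peak polylines.
#' @param waviness_um Amplitude of the spanwise sinusoidal waviness of
#'   each ridge, um.
#' @param n_quadrats Number of sampling quadrats.
#' @param hairs_per_quadrat Hairs measured per quadrat.
#' @param noise_sd_deg Circular standard deviation (degrees) of the
#'   angular noise added to the model orientation for each hair.
#' @param truth A [model_params()]: the ground-truth weights generating
#'   the hair angles.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             length_um = 4000,
                             chord_um = 1600,
                             n_ridges = 5L,
                             waviness_um = 40,
                             n_quadrats = 24L,
                             hairs_per_quadrat = 20L,
                             noise_sd_deg = 10,
                             truth = model_params(0.544, 196)) {
  stopifnot(inherits(truth, "model_params"))
  if (length_um <= chord_um || chord_um <= 0) {
    abort("need wing length > chord > 0.")
  }
  if (n_ridges < 1L || n_quadrats < 1L || hairs_per_quadrat < 1L) {
    abort("counts must be >= 1.")
  }
  if (noise_sd_deg < 0) abort("`noise_sd_deg` must be >= 0.")
  structure(
    list(seed = as.integer(seed), length_um = length_um,
         chord_um = chord_um, n_ridges = as.integer(n_ridges),
         waviness_um = waviness_um, n_quadrats = as.integer(n_quadrats),
         hairs_per_quadrat = as.integer(hairs_per_quadrat),
         noise_sd_deg = noise_sd_deg, truth = truth),
    class = "synthetic_config")
}

#' Generate a synthetic wing geometry
#'
#' Builds a simple closed margin shaped like an elongated, slightly
#' tapered wing (long axis along X, tip at negative X) and the requested
#' number of non-crossing, roughly spanwise ridge polylines inside it.
#' Deterministic for a fixed seed.
#'
#' @param config A [synthetic_config()].
#' @return A [wing_geometry()].
#' @examples
#' geom <- generate_wing(synthetic_config(seed = 42))
#' geom
#' @export
generate_wing <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr_seed(config$seed, {
    a <- config$length_um / 2
    b <- config$chord_um / 2
    th <- seq(0, 2 * pi, length.out = 181)[-181]
    # mild smooth radial modulation: tapered, egg-like outline
    r_mod <- 1 + 0.08 * cos(2 * th) + 0.05 * sin(th)
    margin <- tibble(x = a * cos(th) * r_mod, y = b * sin(th) * r_mod)

    nr <- config$n_ridges
    # ridge heights strictly between the margin extremes
    fr <- seq(-0.75, 0.75, length.out = nr + 2L)[2:(nr + 1L)]
    gap <- if (nr > 1L) diff(fr)[1] * b else b
    if (config$waviness_um >= gap / 2) {
      abort("infeasible ridge count/waviness for the chord: ridges would cross.")
    }
    phase <- runif(nr, 0, 2 * pi)
    ridges <- purrr::map_dfr(seq_len(nr), function(k) {
      y0 <- fr[k] * b
      half_span <- a * sqrt(max(1 - (fr[k])^2, 0)) * 0.82
      xs <- seq(-half_span, half_span, length.out = 40)
      ys <- y0 + config$waviness_um *
        sin(2 * pi * xs / config$length_um * 3 + phase[k])
      tibble(ridge = k, x = xs, y = ys)
    })
    wing_geometry(margin, ridges)
  })
}

#' Sample quadrats with noisy hair orientations from a synthetic wing
#'
#' Quadrat centres are drawn uniformly over the margin's bounding box —
#' not the interior — so that centres occasionally fall off the wing and
#' the out-of-wing exclusion path is exercised, mirroring the sampling of
#' the real specimen. For each quadrat, hair angles are the ground-truth
#' model orientation at the centre plus independent von Mises angular
#' noise with the configured circular standard deviation. A centre where
#' the model orientation is degenerate (exactly cancelling terms) is
#' resampled, with a message.
#'
#' @param geom A [wing_geometry()], typically from [generate_wing()].
#' @param config The same [synthetic_config()].
#' @return A quadrat tibble (see [quadrat_samples()]) with one extra
#'   column `true_phi_deg`, the noise-free model orientation.
#' @export
sample_quadrats <- function(geom, config) {
  stopifnot(inherits(geom, "wing_geometry"),
            inherits(config, "synthetic_config"))
  withr_seed(config$seed + 1L, {
    n <- config$n_quadrats
    bx <- range(geom$margin$x); by <- range(geom$margin$y)
    centres <- tibble(quadrat = seq_len(n), x = double(n), y = double(n))
    true_phi <- double(n)
    for (i in seq_len(n)) {
      repeat {
        p <- tibble(x = runif(1, bx[1], bx[2]), y = runif(1, by[1], by[2]))
        mo <- model_orientation(p, config$truth, geom, degenerate = "flag")
        if (!mo$degenerate) break
        message("resampling quadrat centre with degenerate model orientation")
      }
      centres$x[i] <- p$x; centres$y[i] <- p$y
      true_phi[i] <- mo$phi_deg
    }
    kappa <- vm_kappa(config$noise_sd_deg)
    orientations <- purrr::map_dfr(seq_len(n), function(i) {
      noise <- if (is.infinite(kappa)) {
        rep(0, config$hairs_per_quadrat)
      } else {
        rvonmises(config$hairs_per_quadrat, kappa) * 180 / pi
      }
      tibble(quadrat = i,
             phi_deg = wrap_angle(true_phi[i] + noise))
    })
    out <- quadrat_samples(centres, orientations, geom)
    out$true_phi_deg <- true_phi
    out
  })
}

# von Mises concentration matching a small-angle circular sd (degrees):
# kappa = 1/sigma^2 in radians; sigma = 0 -> point mass.
vm_kappa <- function(sd_deg) {
  if (sd_deg == 0) return(Inf)
  1 / (sd_deg * pi / 180)^2
}

# Best & Fisher (1979) rejection sampler for the von Mises distribution,
# mean 0, concentration kappa; returns radians in (-pi, pi].
rvonmises <- function(n, kappa) {
  if (kappa < 1e-8) return(runif(n, -pi, pi))
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      z <- cos(pi * runif(1))
      f <- (1 + r * z) / (r + z)
      c_ <- kappa * (r - f)
      u <- runif(1)
      if (c_ * (2 - c_) - u > 0 || log(c_ / u) + 1 - c_ >= 0) break
    }
    out[i] <- sign(runif(1) - 0.5) * acos(f)
  }
  out
}

# run code under a temporary seed without disturbing the global RNG state
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
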
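test_that("mean orientation is the circular mean, arithmetic on a half arc", {
  expect_equal(mean_orientation(c(170, 190)), 180)
  expect_equal(mean_orientation(42), 42)
  expect_equal(mean_orientation(c(350, 10)), 0)

  # coincides with the arithmetic mean whenever angles span < 180 degrees
  set.seed(2)
  for (i in 1:20) {
    base <- runif(1, 0, 360)
    a <- base + runif(8, 0, 170)
    expect_equal(mean_orientation(a), wrap_angle(mean(a)), tolerance = 1e-9)
  }

  expect_error(mean_orientation(numeric()), "at least one")
  expect_error(mean_orientation(c(0, 180)), "resultant")
})

test_that("mean orientation is rotation-equivariant", {
  set.seed(3)
  a <- runif(15, 0, 360)
  m <- mean_orientation(a)
  for (alpha in c(10, 123.4, 359)) {
    expect_equal(mean_orientation(a + alpha), wrap_angle(m + alpha),
                 tolerance = 1e-9)
  }
})

test_that("quadrat assembly joins centres and hairs and flags the wing interior", {
  geom <- square_geom(100)
  centres <- data.frame(quadrat = 1:3, x = c(50, 20, 150), y = c(50, 80, 50))
  orient <- data.frame(quadrat = c(1, 1, 1, 2, 2, 2),
                       phi_deg = c(170, 180, 190, 350, 10, 30))
  q <- quadrat_samples(centres, orient, geom)
  expect_equal(q$n_hairs, c(3L, 3L, 0L))
  expect_equal(q$mean_phi_deg[1:2], c(180, mean_orientation(c(350, 10, 30))))
  expect_equal(q$in_wing, c(TRUE, TRUE, FALSE))

  expect_error(
    quadrat_samples(centres, data.frame(quadrat = 9, phi_deg = 0), geom),
    "unknown quadrat")
  expect_error(
    quadrat_samples(rbind(centres, centres[1, ]), orient, geom),
    "duplicate")
})

test_that("bias classifications use strict dot-product sign rules", {
  # horizontal ridge above the point: u-hat = (0, 1); bottom edge nearest
  geom <- rect_geom(ridges = data.frame(ridge = 1, x = c(100, 900),
                                        y = c(300, 300)))
  mk <- function(phi) tibble::tibble(quadrat = 1, x = 500, y = 100,
                                     mean_phi_deg = phi, in_wing = TRUE)
  expect_true(classify_upslope(mk(45), geom)$upslope)
  expect_false(classify_upslope(mk(180), geom)$upslope)  # perpendicular
  expect_false(classify_upslope(mk(315), geom)$upslope)

  # on the ridge the upslope direction is undefined
  on_ridge <- tibble::tibble(quadrat = 1, x = 500, y = 300,
                             mean_phi_deg = 45, in_wing = TRUE)
  expect_true(is.na(classify_upslope(on_ridge, geom)$upslope))

  # nearest edge below: D-hat = (0, -1)
  expect_true(classify_edgeward(mk(270), geom)$edgeward)
  expect_false(classify_edgeward(mk(0), geom)$edgeward)   # perpendicular
  expect_false(classify_edgeward(mk(90), geom)$edgeward)

  expect_true(classify_distal(180))
  expect_false(classify_distal(-87.5))  # slight proximal bias
  expect_false(classify_distal(90))     # perpendicular is not biased
  a <- c(170, 200, 272.5, 10)
  expect_equal(classify_distal(a + 360), classify_distal(a))
})

test_that("exact binomial tails match integer summation and pbinom", {
  expect_equal(binomial_tail(0, 24), 1)
  expect_equal(binomial_tail(24, 24), 2^-24)
  expect_equal(binomial_tail(16, 24), 1271626 / 16777216)
  expect_equal(binomial_tail(18, 23), 44552 / 8388608)
  # complement is exact in integer arithmetic
  for (n in c(10, 23, 24)) {
    for (k in c(1, 5, n)) {
      expect_identical(binomial_tail(k, n) +
                         sum(choose(n, 0:(k - 1))) / 2^n, 1)
      expect_equal(binomial_tail(k, n),
                   pbinom(k - 1, n, 0.5, lower.tail = FALSE),
                   tolerance = 1e-12)
    }
  }
  expect_error(binomial_tail(5, 4), "k")
  summ <- bias_summary(16, 24)
  expect_equal(summ$tail_probability, 1271626 / 16777216)
  expect_equal(summ$fraction, 2 / 3)
})

test_that("distal counts on noiseless synthetic data equal the generator truth", {
  cfg <- synthetic_config(seed = 19, noise_sd_deg = 0)
  geom <- generate_wing(cfg)
  q <- sample_quadrats(geom, cfg)
  hairs <- tidyr::unnest(q[c("quadrat", "angles")], "angles")
  expected <- sum(classify_distal(q$true_phi_deg) * cfg$hairs_per_quadrat)
  expect_equal(sum(classify_distal(hairs$angles)), expected)
})

test_that("residual-vs-distance regression recovers exact and null relations", {
  geom <- rect_geom()
  # residual grows linearly with distance to the bottom edge -> R^2 = 1
  d <- c(20, 60, 100, 140, 180)
  edge_phi <- 270  # direction to the nearest (bottom) edge
  q <- tibble::tibble(quadrat = seq_along(d), x = 500, y = d,
                      mean_phi_deg = wrap_angle(edge_phi + 0.3 * d),
                      in_wing = TRUE)
  fit <- residual_distance_fit(q, geom)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$slope, 0.3, tolerance = 1e-9)
  expect_equal(fit$r, 1, tolerance = 1e-9)

  # residual independent of distance -> r near 0
  set.seed(4)
  d2 <- runif(200, 10, 190)
  q2 <- tibble::tibble(quadrat = seq_along(d2), x = 500, y = d2,
                       mean_phi_deg = wrap_angle(270 + rnorm(200, 20, 2)),
                       in_wing = TRUE)
  fit2 <- residual_distance_fit(q2, geom)
  expect_lt(abs(fit2$r), 0.2)
  expect_error(residual_distance_fit(q[1:2, ], geom), "at least 3")
})

test_that("model fidelity summarizes residuals and variance explained", {
  obs <- tibble::tibble(quadrat = 1:5,
                        phi_deg = c(120, 160, 200, 240, 280))
  perfect <- model_fidelity(obs, obs)
  expect_equal(perfect$r_squared, 1)
  expect_equal(perfect$median_residual, 0)
  expect_equal(perfect$max_residual, 0)
  expect_equal(perfect$frac_below, 1)

  pred <- tibble::tibble(quadrat = 1:3, phi_deg = c(100, 200, 300))
  obs3 <- tibble::tibble(quadrat = 1:3, phi_deg = c(110, 220, 330))
  fid <- model_fidelity(pred, obs3)
  expect_equal(fid$median_residual, 20)
  expect_equal(fid$max_residual, 30)
  expect_equal(fid$frac_below, 2 / 3)

  # wrap-around pairs do not inflate the residuals
  pw <- tibble::tibble(quadrat = 1:2, phi_deg = c(359, 200))
  ow <- tibble::tibble(quadrat = 1:2, phi_deg = c(1, 210))
  expect_equal(model_fidelity(pw, ow)$max_residual, 10)

  expect_error(
    model_fidelity(pred, tibble::tibble(quadrat = 4:6, phi_deg = 1:3)),
    "same quadrats")
})
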
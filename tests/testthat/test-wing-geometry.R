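test_that("nearest point on a polyline handles endpoints, feet and ties", {
  seg <- data.frame(x = c(1, 1), y = c(0, 1))
  ep <- nearest_point_on_polyline(data.frame(x = 0, y = 0), seg)
  expect_equal(c(ep$qx, ep$qy, ep$dist), c(1, 0, 1))

  foot <- nearest_point_on_polyline(data.frame(x = 0, y = 0.5), seg)
  expect_equal(c(foot$qx, foot$qy, foot$dist), c(1, 0.5, 1))

  # square centre is equidistant from all four sides: lowest segment wins
  sq <- square_geom()
  tie <- nearest_point_on_polyline(data.frame(x = 5, y = 5), sq$margin,
                                   closed = TRUE)
  expect_equal(tie$segment, 1L)
  expect_equal(c(tie$qx, tie$qy, tie$dist), c(5, 0, 5))
})

test_that("degenerate polylines are rejected", {
  expect_error(
    nearest_point_on_polyline(data.frame(x = 0, y = 0),
                              data.frame(x = c(1, 1), y = c(2, 2))),
    "duplicate|degenerate")
  expect_error(wing_geometry(data.frame(x = c(0, 1), y = c(0, 0)), NULL),
               "at least 3")
})

test_that("nearest point matches a dense-sampling oracle on random polylines", {
  set.seed(101)
  for (i in 1:100) {
    line <- random_polyline()
    p <- data.frame(x = runif(1, -120, 120), y = runif(1, -120, 120))
    got <- nearest_point_on_polyline(p, line)
    oracle <- nearest_dense_oracle(p, line, samples_per_segment = 5500)
    expect_lte(abs(got$dist - oracle), 1e-3 * oracle + 1e-12)
    expect_gte(oracle, got$dist)  # exact answer can only be closer
  }
})

test_that("edge displacement points to the nearest side and clamps on the margin", {
  geom <- square_geom(10)
  d <- edge_displacement(data.frame(x = 1, y = 5), geom)
  expect_equal(c(d$dx, d$dy), c(-1, 0))
  expect_equal(d$dist, 1)
  expect_false(d$clamped)

  # on the margin: norm clamped to eps, direction outward
  dm <- edge_displacement(data.frame(x = 0, y = 5), geom)
  expect_true(dm$clamped)
  expect_equal(sqrt(dm$dx^2 + dm$dy^2), 0.37)
  expect_equal(sign(dm$dx), -1)  # outward of the left side
  expect_equal(dm$dy, 0)

  # just inside the clamp band: direction preserved, norm raised to eps
  dn <- edge_displacement(data.frame(x = 0.1, y = 5), geom)
  expect_true(dn$clamped)
  expect_equal(c(dn$dx, dn$dy), c(-0.37, 0))
})

test_that("displacement plus point lands on the margin when unclamped", {
  set.seed(7)
  geom <- generate_wing(synthetic_config(seed = 11))
  pts <- data.frame(x = runif(40, -2000, 2000), y = runif(40, -900, 900))
  d <- edge_displacement(pts, geom)
  land <- data.frame(x = pts$x + d$dx, y = pts$y + d$dy)
  back <- nearest_point_on_polyline(land, geom$margin, closed = TRUE)
  expect_lt(max(back$dist[!d$clamped]), 1e-9)
})

test_that("upslope direction points at the nearest ridge, vanishing on a peak", {
  geom <- rect_geom(ridges = data.frame(ridge = 1, x = c(5, 5) * 100,
                                        y = c(0, 400)))  # vertical x=500
  u <- upslope_direction(data.frame(x = 0, y = 200), geom)
  expect_equal(c(u$ux, u$uy), c(1, 0))
  expect_false(u$on_ridge)

  on <- upslope_direction(data.frame(x = 500, y = 200), geom)
  expect_true(on$on_ridge)
  expect_equal(c(on$ux, on$uy), c(0, 0))

  # two equidistant ridges: lowest ridge id wins
  geom2 <- rect_geom(ridges = data.frame(ridge = c(1, 1, 2, 2),
                                         x = c(100, 900, 100, 900),
                                         y = c(300, 300, 100, 100)))
  u2 <- upslope_direction(data.frame(x = 500, y = 200), geom2)
  expect_equal(u2$ridge, 1)
  expect_equal(c(u2$ux, u2$uy), c(0, 1))

  expect_error(
    upslope_direction(data.frame(x = 1, y = 1),
                      wing_geometry(square_geom()$margin, NULL)),
    "no ridge")
})

test_that("point-in-wing uses the even-odd rule with boundary outside", {
  geom <- square_geom(1)
  expect_true(point_in_wing(data.frame(x = 0.5, y = 0.5), geom))
  expect_false(point_in_wing(data.frame(x = 2, y = 2), geom))
  expect_false(point_in_wing(data.frame(x = 0, y = 0.5), geom))   # boundary
  expect_false(point_in_wing(data.frame(x = 0, y = 0), geom))     # vertex
})

test_that("point-in-wing agrees with an independent polygon test off-boundary", {
  skip_if_not_installed("mgcv")
  set.seed(5)
  geom <- generate_wing(synthetic_config(seed = 21))
  pts <- data.frame(x = runif(300, -2200, 2200), y = runif(300, -1000, 1000))
  near <- nearest_point_on_polyline(pts, geom$margin, closed = TRUE)
  keep <- near$dist > 1e-6  # away from the boundary convention
  got <- point_in_wing(pts, geom)
  bnd <- as.matrix(rbind(geom$margin, geom$margin[1, ]))
  ref <- mgcv::in.out(bnd, as.matrix(pts))
  expect_equal(got[keep], ref[keep])
})

test_that("rigid rotation rotates D and u by the same angle", {
  set.seed(31)
  geom <- generate_wing(synthetic_config(seed = 31))
  pts <- data.frame(x = runif(20, -1500, 1500), y = runif(20, -600, 600))
  d0 <- edge_displacement(pts, geom)
  u0 <- upslope_direction(pts, geom)
  alpha <- 37.3
  rot <- function(df) trichor:::rotate_xy(df, alpha)
  geom_r <- wing_geometry(rot(geom$margin), rot(geom$ridges))
  pts_r <- rot(pts)
  d1 <- edge_displacement(pts_r, geom_r)
  u1 <- upslope_direction(pts_r, geom_r)
  d0r <- trichor:::rotate_xy(data.frame(x = d0$dx, y = d0$dy), alpha)
  u0r <- trichor:::rotate_xy(data.frame(x = u0$ux, y = u0$uy), alpha)
  nd <- sqrt(d0$dx^2 + d0$dy^2)
  expect_lt(max(abs(d1$dx / nd - d0r$x / nd),
                abs(d1$dy / nd - d0r$y / nd)), 1e-9)
  expect_lt(max(abs(u1$ux - u0r$x), abs(u1$uy - u0r$y)), 1e-9)
})

test_that("uniform scaling scales ||D|| and leaves u unchanged", {
  geom <- generate_wing(synthetic_config(seed = 41))
  pts <- data.frame(x = c(-800, 200, 900), y = c(-200, 100, 300))
  s <- 3.5
  geom_s <- wing_geometry(
    data.frame(x = geom$margin$x * s, y = geom$margin$y * s),
    data.frame(ridge = geom$ridges$ridge, x = geom$ridges$x * s,
               y = geom$ridges$y * s))
  d0 <- edge_displacement(pts, geom)
  d1 <- edge_displacement(data.frame(x = pts$x * s, y = pts$y * s), geom_s)
  expect_equal(d1$dist, s * d0$dist, tolerance = 1e-12)
  u0 <- upslope_direction(pts, geom)
  u1 <- upslope_direction(data.frame(x = pts$x * s, y = pts$y * s), geom_s)
  expect_equal(c(u1$ux, u1$uy), c(u0$ux, u0$uy), tolerance = 1e-12)
})

test_that("ridge vertices outside the margin warn but do not fail", {
  expect_warning(
    wing_geometry(data.frame(x = c(0, 10, 10, 0), y = c(0, 0, 10, 10)),
                  data.frame(ridge = 1, x = c(5, 15), y = c(5, 5))),
    "outside")
  expect_error(
    wing_geometry(data.frame(x = c(0, 10, 0, 10), y = c(0, 0, 10, 10)),
                  NULL),
    "simple")
})
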
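# Shared fixtures: small geometries with hand-checkable nearest-feature
# answers, and a random-polyline generator for oracle comparisons.

# 1000 x 400 um rectangle, one vertical ridge segment at x = 900 and one
# horizontal ridge at y = 300 available on demand.
rect_geom <- function(ridges = data.frame(ridge = 1, x = c(900, 900),
                                          y = c(100, 300))) {
  wing_geometry(
    margin = data.frame(x = c(0, 1000, 1000, 0), y = c(0, 0, 400, 400)),
    ridges = ridges
  )
}

# unit square margin with a diagonal ridge (rarely used for ridge queries)
square_geom <- function(side = 10) {
  wing_geometry(
    margin = data.frame(x = c(0, side, side, 0), y = c(0, 0, side, side)),
    ridges = data.frame(ridge = 1, x = c(side * 0.2, side * 0.8),
                        y = c(side * 0.5, side * 0.5))
  )
}

random_polyline <- function(n_vertices = 20, range = 100) {
  data.frame(x = runif(n_vertices, -range, range),
             y = runif(n_vertices, -range, range))
}

# dense-sampling oracle: min distance from p to `samples_per_segment`
# points spread along every segment of the polyline
nearest_dense_oracle <- function(p, line, samples_per_segment = 5000) {
  n <- nrow(line)
  best <- Inf
  for (i in seq_len(n - 1)) {
    t <- seq(0, 1, length.out = samples_per_segment)
    qx <- line$x[i] + t * (line$x[i + 1] - line$x[i])
    qy <- line$y[i] + t * (line$y[i + 1] - line$y[i])
    best <- min(best, sqrt((p$x - qx)^2 + (p$y - qy)^2))
  }
  best
}

# angular distance between two unit vectors given as angle columns
unit_vec <- function(phi_deg) {
  a <- phi_deg * pi / 180
  cbind(cos(a), sin(a))
}
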
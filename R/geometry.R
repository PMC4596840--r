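#' Assemble a planar wing geometry
#'
#' A wing geometry holds the digitized wing outline (a closed polygon, the
#' *margin*), the ridge-peak polylines (local topographic maxima of the
#' corrugated wing surface), the pixel-to-micrometre scale of the source
#' image, and the fixed distal unit vector. All internal coordinates are in
#' micrometres with the Y axis pointing up; positive X points proximally
#' (toward the body), so the distal direction is `(-1, 0)`.
#'
#' @param margin Data frame with columns `x`, `y` (um): the closed wing
#'   outline. The last vertex need not repeat the first; closure is implied.
#' @param ridges Data frame with columns `ridge`, `x`, `y` (um): one open
#'   polyline per ridge-peak line, identified by `ridge`.
#' @param scale Micrometres per pixel of the source image. Used by the CSV
#'   readers/writers; geometry passed here is already in micrometres.
#' @param distal Unit vector of the distal direction. Default `c(-1, 0)`.
#'
#' @return An object of class `wing_geometry`: a list with tibbles `margin`
#'   and `ridges`, the `scale`, and `distal`.
#' @examples
#' geom <- wing_geometry(
#'   margin = data.frame(x = c(0, 10, 10, 0), y = c(0, 0, 10, 10)),
#'   ridges = data.frame(ridge = 1, x = c(1, 9), y = c(5, 5))
#' )
#' geom
#' @export
wing_geometry <- function(margin, ridges,
                          scale = DEFAULT_SCALE_UM_PER_PX,
                          distal = c(-1, 0)) {
  margin <- as_tibble(margin)
  if (!all(c("x", "y") %in% names(margin))) {
    abort("`margin` must have columns `x` and `y`.")
  }
  margin <- margin[c("x", "y")]
  if (!all(is.finite(margin$x)) || !all(is.finite(margin$y))) {
    abort("`margin` coordinates must be finite.")
  }
  # drop an explicit closing vertex; closure is implied
  n <- nrow(margin)
  if (n >= 2 && margin$x[1] == margin$x[n] && margin$y[1] == margin$y[n]) {
    margin <- margin[-n, ]
  }
  if (nrow(margin) < 3L) abort("`margin` needs at least 3 distinct vertices.")
  check_polyline(margin$x, margin$y, closed = TRUE)
  if (!is_simple_polygon(margin$x, margin$y)) {
    abort("`margin` must be a simple (non-self-intersecting) polygon.")
  }

  if (is.null(ridges) || nrow(ridges) == 0L) {
    ridges <- tibble(ridge = integer(), x = double(), y = double())
  } else {
    ridges <- as_tibble(ridges)
    if (!all(c("ridge", "x", "y") %in% names(ridges))) {
      abort("`ridges` must have columns `ridge`, `x` and `y`.")
    }
    ridges <- ridges[c("ridge", "x", "y")]
    if (!all(is.finite(ridges$x)) || !all(is.finite(ridges$y))) {
      abort("`ridges` coordinates must be finite.")
    }
    for (id in unique(ridges$ridge)) {
      sub <- ridges[ridges$ridge == id, ]
      check_polyline(sub$x, sub$y, closed = FALSE,
                     what = paste0("ridge ", id))
    }
  }

  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0) {
    abort("`scale` must be a single positive number (um per px).")
  }
  nb <- sqrt(sum(distal^2))
  if (length(distal) != 2L || !all(is.finite(distal)) || nb == 0) {
    abort("`distal` must be a finite non-zero 2-vector.")
  }
  distal <- distal / nb

  geom <- structure(
    list(margin = margin, ridges = ridges, scale = scale, distal = distal),
    class = "wing_geometry"
  )
  if (nrow(ridges) > 0L) {
    inside <- point_in_wing(ridges, geom)
    on_edge <- edge_displacement(ridges, geom)$dist <= EPS_CLAMP_UM
    if (any(!inside & !on_edge)) {
      warn(sprintf("%d ridge vertex(es) lie outside the wing margin.",
                   sum(!inside & !on_edge)))
    }
  }
  geom
}

#' @export
print.wing_geometry <- function(x, ...) {
  cat(sprintf(
    "<wing_geometry> margin: %d vertices; ridges: %d polyline(s), %d vertices; scale %.5f um/px\n",
    nrow(x$margin), length(unique(x$ridges$ridge)), nrow(x$ridges), x$scale))
  invisible(x)
}

check_polyline <- function(x, y, closed, what = "polyline") {
  n <- length(x)
  if (n < 2L) abort(sprintf("%s needs at least 2 points.", what))
  xs <- c(x, if (closed) x[1])
  ys <- c(y, if (closed) y[1])
  if (any(diff(xs) == 0 & diff(ys) == 0)) {
    abort(sprintf("%s has consecutive duplicate points.", what))
  }
  if (length(unique(paste(x, y))) == 1L) {
    abort(sprintf("%s is degenerate: all points identical.", what))
  }
  invisible(TRUE)
}

# Segment-intersection test of every non-adjacent pair (O(n^2); the margins
# handled here have a few hundred vertices).
is_simple_polygon <- function(x, y) {
  n <- length(x)
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    # skip segments sharing a vertex with i (j = i+1 and the wrap pair 1,n)
    js <- js[js != i + 1L & !(i == 1L & js == n)]
    if (!length(js)) next
    if (any(segments_intersect(x[i], y[i], x2[i], y2[i],
                               x[js], y[js], x2[js], y2[js]))) {
      return(FALSE)
    }
  }
  TRUE
}

segments_intersect <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  d1 <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  d2 <- (bx - ax) * (dy - ay) - (by - ay) * (dx - ax)
  d3 <- (dx - cx) * (ay - cy) - (dy - cy) * (ax - cx)
  d4 <- (dx - cx) * (by - cy) - (dy - cy) * (bx - cx)
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

#' Nearest point on a polyline
#'
#' For each query point, finds the closest point lying on any segment of the
#' polyline (vertices included). Distance ties are broken toward the lowest
#' segment index, then the smallest parameter along the segment, so results
#' are deterministic even at symmetric configurations.
#'
#' @param points Data frame with columns `x`, `y`: query points.
#' @param line Data frame with columns `x`, `y`: polyline vertices in order.
#' @param closed Treat the polyline as closed (append the segment from last
#'   to first vertex)? Default `FALSE`.
#'
#' @return A tibble with one row per query point: `qx`, `qy` (the nearest
#'   point), `dist`, and `segment` (1-based index of the winning segment).
#' @examples
#' nearest_point_on_polyline(data.frame(x = 0, y = 0.5),
#'                           data.frame(x = c(1, 1), y = c(0, 1)))
#' @export
nearest_point_on_polyline <- function(points, line, closed = FALSE) {
  points <- as_tibble(points)
  lx <- line$x
  ly <- line$y
  check_polyline(lx, ly, closed = closed)
  if (closed) {
    lx <- c(lx, lx[1])
    ly <- c(ly, ly[1])
  }
  ax <- lx[-length(lx)]; ay <- ly[-length(ly)]
  bx <- lx[-1];          by <- ly[-1]
  vx <- bx - ax; vy <- by - ay
  len2 <- vx^2 + vy^2

  n <- nrow(points)
  out_qx <- out_qy <- out_d <- numeric(n)
  out_seg <- integer(n)
  for (i in seq_len(n)) {
    px <- points$x[i]; py <- points$y[i]
    t <- ((px - ax) * vx + (py - ay) * vy) / len2
    t[len2 == 0] <- 0
    t <- pmin(pmax(t, 0), 1)
    qx <- ax + t * vx
    qy <- ay + t * vy
    d2 <- (px - qx)^2 + (py - qy)^2
    j <- which.min(d2)  # first minimum -> lowest segment index
    out_qx[i] <- qx[j]; out_qy[i] <- qy[j]
    out_d[i] <- sqrt(d2[j]); out_seg[i] <- j
  }
  tibble(qx = out_qx, qy = out_qy, dist = out_d, segment = out_seg)
}

#' Displacement to the nearest wing edge
#'
#' Computes `D(x, y)`, the displacement vector from each query point to the
#' nearest point on the wing margin. Its norm is clamped below at
#' `eps` = 0.37 um (half a pixel of the reference image) so that the
#' edge-attraction term of the orientation model, which scales as
#' `1 / ||D||`, stays finite on the margin itself. For a point lying exactly
#' on the margin the clamped displacement points outward (away from the wing
#' interior), continuing the limit from inside.
#'
#' @param points Data frame with columns `x`, `y` (um).
#' @param geom A [wing_geometry()].
#' @param eps Lower clamp on `||D||` in um.
#'
#' @return A tibble with one row per point: `dx`, `dy` (the clamped
#'   displacement, um), `dist` (the *unclamped* distance to the margin, um),
#'   and `clamped` (logical).
#' @export
edge_displacement <- function(points, geom, eps = EPS_CLAMP_UM) {
  stopifnot(inherits(geom, "wing_geometry"))
  points <- as_tibble(points)
  np <- nearest_point_on_polyline(points, geom$margin, closed = TRUE)
  dx <- np$qx - points$x
  dy <- np$qy - points$y
  d <- np$dist
  clamped <- d < eps
  for (i in which(clamped)) {
    if (d[i] > DEGENERATE_NORM_TOL) {
      dx[i] <- dx[i] / d[i] * eps
      dy[i] <- dy[i] / d[i] * eps
    } else {
      # exactly on the margin: use the outward normal of the nearest segment
      nrm <- outward_normal(geom, np$segment[i])
      dx[i] <- nrm[1] * eps
      dy[i] <- nrm[2] * eps
    }
  }
  tibble(dx = dx, dy = dy, dist = d, clamped = clamped)
}

# Unit normal of margin segment `seg` pointing away from the wing interior.
outward_normal <- function(geom, seg) {
  mx <- c(geom$margin$x, geom$margin$x[1])
  my <- c(geom$margin$y, geom$margin$y[1])
  vx <- mx[seg + 1L] - mx[seg]
  vy <- my[seg + 1L] - my[seg]
  len <- sqrt(vx^2 + vy^2)
  nrm <- c(-vy, vx) / len
  mid <- c((mx[seg] + mx[seg + 1L]) / 2, (my[seg] + my[seg + 1L]) / 2)
  probe <- mid + nrm * len * 1e-6
  if (point_in_wing(tibble(x = probe[1], y = probe[2]), geom)) -nrm else nrm
}

#' Local upslope direction (proxy: toward the nearest ridge peak)
#'
#' The direction from a point to the globally nearest point across all
#' ridge-peak polylines is used as a proxy for the local upslope gradient of
#' the corrugated wing surface. Within `eps` = 0.37 um of a ridge the point
#' is considered to sit on the peak and the upslope direction vanishes (zero
#' vector). Ties between equidistant ridges are broken toward the lowest
#' ridge identifier, then the lowest segment index.
#'
#' @inheritParams edge_displacement
#' @return A tibble with one row per point: `ux`, `uy` (unit vector, or zero
#'   on a ridge), `dist` (distance to the nearest ridge, um), `ridge` (the
#'   winning ridge id) and `on_ridge` (logical).
#' @export
upslope_direction <- function(points, geom, eps = EPS_CLAMP_UM) {
  stopifnot(inherits(geom, "wing_geometry"))
  points <- as_tibble(points)
  ids <- unique(geom$ridges$ridge)
  if (length(ids) == 0L) abort("geometry has no ridge polylines.")
  per <- lapply(ids, function(id) {
    sub <- geom$ridges[geom$ridges$ridge == id, ]
    nearest_point_on_polyline(points, sub, closed = FALSE)
  })
  n <- nrow(points)
  ux <- uy <- dist <- numeric(n)
  ridge <- vector(mode = typeof(ids), n)
  for (i in seq_len(n)) {
    ds <- vapply(per, function(np) np$dist[i], numeric(1))
    j <- which.min(ds)  # first minimum -> lowest ridge index
    np <- per[[j]]
    d <- np$dist[i]
    dist[i] <- d
    ridge[i] <- ids[j]
    if (d < eps) {
      ux[i] <- 0; uy[i] <- 0
    } else {
      ux[i] <- (np$qx[i] - points$x[i]) / d
      uy[i] <- (np$qy[i] - points$y[i]) / d
    }
  }
  tibble(ux = ux, uy = uy, dist = dist, ridge = ridge,
         on_ridge = dist < eps)
}

#' Is a point strictly inside the wing margin?
#'
#' Even-odd (ray-casting) point-in-polygon test. Points on the margin
#' boundary are classified *outside*: the analyses that exclude out-of-wing
#' quadrats treat the boundary conservatively.
#'
#' @inheritParams edge_displacement
#' @param tol Points within `tol` um of the margin are treated as boundary
#'   (hence outside).
#' @return Logical vector, one element per point.
#' @export
point_in_wing <- function(points, geom, tol = 1e-9) {
  stopifnot(inherits(geom, "wing_geometry"))
  points <- as_tibble(points)
  mx <- geom$margin$x
  my <- geom$margin$y
  n <- length(mx)
  jx <- c(mx[n], mx[-n]); jy <- c(my[n], my[-n])
  on_boundary <- nearest_point_on_polyline(points, geom$margin,
                                           closed = TRUE)$dist <= tol
  inside <- vapply(seq_len(nrow(points)), function(i) {
    px <- points$x[i]; py <- points$y[i]
    crosses <- ((my > py) != (jy > py)) &
      (px < (jx - mx) * (py - my) / (jy - my) + mx)
    sum(crosses) %% 2L == 1L
  }, logical(1))
  inside & !on_boundary
}

rotate_xy <- function(df, alpha_deg, cols = c("x", "y")) {
  a <- alpha_deg * pi / 180
  x <- df[[cols[1]]]; y <- df[[cols[2]]]
  df[[cols[1]]] <- cos(a) * x - sin(a) * y
  df[[cols[2]]] <- sin(a) * x + cos(a) * y
  df
}
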
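# Planar geometry primitives used throughout the package. All coordinates are
# Cartesian statute miles; polygons are n x 2 matrices of vertices (open ring,
# i.e. the closing edge last->first is implicit). Convexity is not assumed
# unless stated.

#' Area of a simple polygon
#'
#' Shoelace formula. Returns the unsigned area; vertex orientation does not
#' matter.
#'
#' @param xy Numeric matrix with two columns (x, y) of polygon vertices.
#' @return Area in squared coordinate units.
#' @keywords internal
polygon_area <- function(xy) {
  n <- nrow(xy)
  if (is.null(n) || n < 3) return(0)
  j <- c(2:n, 1L)
  abs(sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2])) / 2
}

#' Centroid of a simple polygon
#' @param xy Vertex matrix.
#' @return Length-2 numeric (x, y).
#' @keywords internal
polygon_centroid <- function(xy) {
  n <- nrow(xy)
  j <- c(2:n, 1L)
  cr <- xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2]
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(xy))
  c(sum((xy[, 1] + xy[j, 1]) * cr), sum((xy[, 2] + xy[j, 2]) * cr)) / (6 * a)
}

# Clip a polygon against the half-plane {p : nx*x + ny*y <= c}
# (one Sutherland-Hodgman pass). Returns possibly empty vertex matrix.
clip_halfplane <- function(xy, nx, ny, c) {
  n <- nrow(xy)
  if (is.null(n) || n == 0) return(matrix(numeric(0), 0, 2))
  d <- xy[, 1] * nx + xy[, 2] * ny - c
  keep <- vector("list", 2L * n)
  m <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (d[i] <= 0) {
      m <- m + 1L
      keep[[m]] <- xy[i, ]
    }
    if ((d[i] < 0 && d[j] > 0) || (d[i] > 0 && d[j] < 0)) {
      t <- d[i] / (d[i] - d[j])
      m <- m + 1L
      keep[[m]] <- xy[i, ] + t * (xy[j, ] - xy[i, ])
    }
  }
  if (m == 0L) return(matrix(numeric(0), 0, 2))
  do.call(rbind, keep[seq_len(m)])
}

#' Test points against a simple polygon
#'
#' Vectorised ray casting. Points exactly on an edge may land on either side;
#' callers treat boundaries as measure zero.
#'
#' @param px,py Point coordinates (equal length).
#' @param xy Vertex matrix.
#' @return Logical vector.
#' @keywords internal
point_in_polygon <- function(px, py, xy) {
  n <- nrow(xy)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- xy[i, 1]; yi <- xy[i, 2]
    xj <- xy[j, 1]; yj <- xy[j, 2]
    hit <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, hit)
    j <- i
  }
  inside
}

# Signed area of the intersection of the disc of radius r centred at the
# origin with the triangle (0, p1, p2). The segment p1->p2 is split at its
# circle crossings; chord pieces inside the disc contribute triangle area,
# pieces outside contribute the circular sector spanned at the origin.
.disc_tri <- function(x1, y1, x2, y2, r) {
  dx <- x2 - x1; dy <- y2 - y1
  a <- dx * dx + dy * dy
  if (a == 0) return(0)
  b <- 2 * (x1 * dx + y1 * dy)
  cc <- x1 * x1 + y1 * y1 - r * r
  ts <- numeric(0)
  disc <- b * b - 4 * a * cc
  if (disc > 0) {
    sq <- sqrt(disc)
    t12 <- c((-b - sq) / (2 * a), (-b + sq) / (2 * a))
    ts <- t12[t12 > 0 & t12 < 1]
  }
  knots <- c(0, ts, 1)
  acc <- 0
  for (k in seq_len(length(knots) - 1L)) {
    t0 <- knots[k]; t1 <- knots[k + 1L]
    tm <- (t0 + t1) / 2
    mx <- x1 + tm * dx; my <- y1 + tm * dy
    ax <- x1 + t0 * dx; ay <- y1 + t0 * dy
    bx <- x1 + t1 * dx; by <- y1 + t1 * dy
    if (mx * mx + my * my <= r * r) {
      acc <- acc + (ax * by - ay * bx) / 2
    } else {
      ang <- atan2(by, bx) - atan2(ay, ax)
      # triangle's angle at the origin is < pi, so wrap into (-pi, pi)
      if (ang > pi) ang <- ang - 2 * pi
      if (ang < -pi) ang <- ang + 2 * pi
      acc <- acc + r * r * ang / 2
    }
  }
  acc
}

#' Exact area of a disc-polygon intersection
#'
#' Decomposes the polygon into origin-anchored triangles (Green's theorem) and
#' intersects each with the disc analytically, so the result is exact to
#' floating point -- a full interior disc yields `pi * r^2`, a disc bisected by
#' a straight boundary yields `pi * r^2 / 2`.
#'
#' @param cx,cy Disc centre.
#' @param r Disc radius (> 0).
#' @param xy Polygon vertex matrix (simple; either orientation).
#' @return Intersection area (non-negative).
#' @keywords internal
disc_polygon_area <- function(cx, cy, r, xy) {
  n <- nrow(xy)
  if (is.null(n) || n < 3 || r <= 0) return(0)
  px <- xy[, 1] - cx
  py <- xy[, 2] - cy
  total <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    total <- total + .disc_tri(px[i], py[i], px[j], py[j], r)
  }
  abs(total)
}
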
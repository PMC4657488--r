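# Planar polygon geometry in projected km coordinates.
#
# All polygons are two-column matrices (x, y) of vertices, implicitly closed
# (last vertex joins the first). No geodesy anywhere: the study-area scale
# makes a single projected planar system with km units adequate, and no
# full GIS stack is assumed.

#' Polygon area by the shoelace formula
#'
#' @param poly two-column matrix of vertices (km), implicitly closed.
#' @return area in km^2 (always non-negative).
#' @export
polygon_area <- function(poly) {
  poly <- as.matrix(poly)
  if (nrow(poly) < 3) stop("polygon needs at least 3 vertices")
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Test points against a polygon (even-odd ray casting)
#'
#' Points exactly on an edge are treated as inside, so partitioning polygons
#' assign boundary points to the first polygon tested (file order).
#'
#' @param px,py point coordinates (km), vectorised.
#' @param poly two-column vertex matrix.
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  vapply(seq_along(px), function(i) {
    x <- px[i]; y <- py[i]
    # on-edge check
    on <- any(
      (pmin(x1, x2) - 1e-12 <= x) & (x <= pmax(x1, x2) + 1e-12) &
      (pmin(y1, y2) - 1e-12 <= y) & (y <= pmax(y1, y2) + 1e-12) &
      abs((x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)) < 1e-9
    )
    if (on) return(TRUE)
    crosses <- ((y1 > y) != (y2 > y)) &
      (x < (x2 - x1) * (y - y1) / (y2 - y1) + x1)
    sum(crosses) %% 2L == 1L
  }, logical(1))
}

# Does the closed polygon self-intersect (bow-tie)? O(n^2) segment check;
# adjacent edges share endpoints and are skipped.
is_simple_polygon <- function(poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  a1 <- poly
  a2 <- poly[c(2:n, 1), , drop = FALSE]
  seg_intersects <- function(p1, p2, q1, q2) {
    d1 <- p2 - p1; d2 <- q2 - q1
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-14) return(FALSE)  # parallel: ignore overlap edge case
    t <- ((q1[1] - p1[1]) * d2[2] - (q1[2] - p1[2]) * d2[1]) / den
    u <- ((q1[1] - p1[1]) * d1[2] - (q1[2] - p1[2]) * d1[1]) / den
    eps <- 1e-12
    t > eps && t < 1 - eps && u > eps && u < 1 - eps
  }
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      if (seg_intersects(a1[i, ], a2[i, ], a1[j, ], a2[j, ])) return(FALSE)
    }
  }
  TRUE
}

#' Convex hull of a point set
#'
#' @param xy two-column matrix of points.
#' @return vertex matrix in counter-clockwise order.
#' @export
convex_hull <- function(xy) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 3) stop("need at least 3 points for a hull")
  h <- grDevices::chull(xy)  # clockwise
  hull <- xy[rev(h), , drop = FALSE]
  if (nrow(hull) < 3 || polygon_area(hull) < 1e-12)
    stop("camera points are collinear; hull has no area")
  hull
}

# Minkowski buffer of a convex CCW polygon by radius w, approximating corner
# arcs with steps of arc_deg degrees. w = 0 returns the polygon unchanged.
buffer_convex <- function(poly, w, arc_deg = 1) {
  if (w < 0) stop("buffer width must be >= 0")
  poly <- as.matrix(poly)
  if (w == 0) return(poly)
  n <- nrow(poly)
  nxt <- c(2:n, 1)
  out <- list()
  for (i in seq_len(n)) {
    p <- poly[i, ]
    e_in <- p - poly[if (i == 1) n else i - 1, ]
    e_out <- poly[nxt[i], ] - p
    # outward normal of CCW edge (ex, ey) is (ey, -ex)
    a1 <- atan2(-e_in[1], e_in[2])
    a2 <- atan2(-e_out[1], e_out[2])
    if (a2 < a1) a2 <- a2 + 2 * pi
    ang <- seq(a1, a2, by = arc_deg * pi / 180)
    if (ang[length(ang)] < a2) ang <- c(ang, a2)
    out[[i]] <- cbind(p[1] + w * cos(ang), p[2] + w * sin(ang))
  }
  do.call(rbind, out)
}

# Sutherland-Hodgman clipping of an arbitrary simple subject polygon against
# a convex CCW clip polygon; returns the intersection polygon (possibly with
# zero rows).
clip_polygon <- function(subject, clip) {
  subject <- as.matrix(subject)
  clip <- as.matrix(clip)
  n <- nrow(clip)
  out <- subject
  for (i in seq_len(n)) {
    if (nrow(out) == 0) return(out)
    a <- clip[i, ]
    b <- clip[if (i == n) 1 else i + 1, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    inside <- function(p) ex * (p[2] - a[2]) - ey * (p[1] - a[1]) >= -1e-12
    inter <- function(p, q) {
      dx <- q[1] - p[1]; dy <- q[2] - p[2]
      den <- ex * dy - ey * dx
      t <- (ex * (a[2] - p[2]) - ey * (a[1] - p[1])) / den
      c(p[1] + t * dx, p[2] + t * dy)
    }
    inp <- out
    m <- nrow(inp)
    res <- vector("list", 2L * m)
    k <- 0L
    for (j in seq_len(m)) {
      p <- inp[j, ]
      q <- inp[if (j == m) 1 else j + 1, ]
      pin <- inside(p); qin <- inside(q)
      if (pin) { k <- k + 1L; res[[k]] <- p }
      if (pin != qin) { k <- k + 1L; res[[k]] <- inter(p, q) }
    }
    out <- if (k == 0L) matrix(numeric(0), 0, 2) else
      do.call(rbind, res[seq_len(k)])
  }
  out
}
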
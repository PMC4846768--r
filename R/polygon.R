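#' Planar polygon utilities
#'
#' Polygons are the common currency of the package: model curves, extracted
#' seed outlines and clipped overlap regions are all closed vertex chains.
#' A polygon is stored as a plain list with numeric vectors `x` and `y`
#' (class `"seed_polygon"`), closed implicitly (the last vertex connects to
#' the first) and oriented counter-clockwise.
#'
#' @param x,y numeric vectors of vertex coordinates, equal length >= 3.
#' @return An object of class `seed_polygon`.
#' @examples
#' sq <- polygon_xy(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' poly_area(sq)
#' @export
polygon_xy <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L)
    stop("a polygon needs at least 3 vertices", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("polygon coordinates must be finite", call. = FALSE)
  # drop duplicated consecutive vertices (incl. a repeated closing vertex)
  n <- length(x)
  keep <- c(TRUE, x[-1] != x[-n] | y[-1] != y[-n])
  if (x[n] == x[1] && y[n] == y[1]) keep[n] <- FALSE
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L)
    stop("degenerate polygon: fewer than 3 distinct vertices", call. = FALSE)
  p <- structure(list(x = as.numeric(x), y = as.numeric(y)),
                 class = "seed_polygon")
  if (poly_signed_area(p) == 0)
    stop("degenerate polygon: zero signed area", call. = FALSE)
  ensure_ccw(p)
}

#' @export
print.seed_polygon <- function(x, ...) {
  cat(sprintf("<seed_polygon> %d vertices, area %.6g, perimeter %.6g\n",
              length(x$x), poly_area(x), poly_perimeter(x)))
  invisible(x)
}

as_poly_list <- function(p) list(x = p$x, y = p$y)

#' Signed (shoelace) area of a polygon
#'
#' Positive for counter-clockwise vertex order.
#' @param p a `seed_polygon` (or list with `x`, `y`).
#' @return scalar signed area.
#' @export
poly_signed_area <- function(p) {
  x <- p$x; y <- p$y
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Absolute polygon area
#' @inheritParams poly_signed_area
#' @export
poly_area <- function(p) abs(poly_signed_area(p))

#' Polygon perimeter (sum of edge lengths)
#' @inheritParams poly_signed_area
#' @export
poly_perimeter <- function(p) {
  x <- p$x; y <- p$y
  sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
}

#' Area centroid of a polygon
#' @inheritParams poly_signed_area
#' @return numeric length-2 vector `c(x, y)`.
#' @export
poly_centroid <- function(p) {
  x <- p$x; y <- p$y
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  w <- x * yn - xn * y
  a <- sum(w) / 2
  c(sum((x + xn) * w), sum((y + yn) * w)) / (6 * a)
}

ensure_ccw <- function(p) {
  if (poly_signed_area(p) < 0) {
    p$x <- rev(p$x); p$y <- rev(p$y)
  }
  p
}

#' Second-order central moments of a polygon region
#'
#' Area-normalised central moments (the covariance of the uniform measure on
#' the polygon interior), computed exactly by Green's theorem. These drive
#' the moment-matched fitted ellipse and principal-axis alignment.
#'
#' @inheritParams poly_signed_area
#' @return list with `mu20`, `mu02`, `mu11`, `centroid`, `area`.
#' @export
poly_moments <- function(p) {
  x <- p$x; y <- p$y
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  w <- x * yn - xn * y
  a <- sum(w) / 2
  cx <- sum((x + xn) * w) / (6 * a)
  cy <- sum((y + yn) * w) / (6 * a)
  # raw second moments about the origin, per unit area
  ixx <- sum(w * (x^2 + x * xn + xn^2)) / 12 / a
  iyy <- sum(w * (y^2 + y * yn + yn^2)) / 12 / a
  ixy <- sum(w * (x * yn + 2 * x * y + 2 * xn * yn + xn * y)) / 24 / a
  list(mu20 = ixx - cx^2, mu02 = iyy - cy^2, mu11 = ixy - cx * cy,
       centroid = c(cx, cy), area = abs(a))
}

#' Principal-axis orientation and equivalent-ellipse axes
#'
#' Orientation is the angle (radians, in (-pi/2, pi/2]) of the major
#' principal axis of the region's second moments. Axis lengths are the full
#' axes (diameters) of the ellipse with the same second moments.
#'
#' @inheritParams poly_signed_area
#' @return list with `orientation`, `major`, `minor` (full lengths).
#' @export
poly_principal_axes <- function(p) {
  m <- poly_moments(p)
  tr <- m$mu20 + m$mu02
  det <- m$mu20 * m$mu02 - m$mu11^2
  disc <- sqrt(max(0, (tr / 2)^2 - det))
  l1 <- tr / 2 + disc
  l2 <- max(0, tr / 2 - disc)
  theta <- 0.5 * atan2(2 * m$mu11, m$mu20 - m$mu02)
  list(orientation = theta, major = 4 * sqrt(l1), minor = 4 * sqrt(l2))
}

#' Rigid and affine polygon transforms
#'
#' `poly_translate`, `poly_rotate` (about a point, default the centroid) and
#' `poly_scale` (isotropic, about a point) return transformed copies.
#'
#' @param p a `seed_polygon`.
#' @param dx,dy translation offsets.
#' @param theta rotation angle in radians (counter-clockwise).
#' @param factor scale factor (> 0).
#' @param center point `c(x, y)` the rotation/scaling is applied about;
#'   default is the polygon centroid.
#' @name poly-transforms
NULL

#' @rdname poly-transforms
#' @export
poly_translate <- function(p, dx, dy) {
  p$x <- p$x + dx; p$y <- p$y + dy
  p
}

#' @rdname poly-transforms
#' @export
poly_rotate <- function(p, theta, center = poly_centroid(p)) {
  ct <- cos(theta); st <- sin(theta)
  x <- p$x - center[1]; y <- p$y - center[2]
  p$x <- center[1] + ct * x - st * y
  p$y <- center[2] + st * x + ct * y
  p
}

#' @rdname poly-transforms
#' @export
poly_scale <- function(p, factor, center = poly_centroid(p)) {
  if (!is.numeric(factor) || factor <= 0)
    stop("scale factor must be positive", call. = FALSE)
  p$x <- center[1] + factor * (p$x - center[1])
  p$y <- center[2] + factor * (p$y - center[2])
  p
}

#' Reflect a polygon across a horizontal line
#'
#' Used to resolve the mirror ambiguity during model alignment; orientation
#' is restored to counter-clockwise after the flip.
#' @param p a `seed_polygon`.
#' @param y0 the y value of the mirror line; default the centroid height.
#' @export
poly_flip_y <- function(p, y0 = poly_centroid(p)[2]) {
  p$y <- 2 * y0 - p$y
  ensure_ccw(p)
}

#' Stretch a polygon along one axis
#'
#' Multiplies the named coordinate of every vertex by `factor`, about the
#' polygon centroid. This is the anisotropic elongation used to build
#' golden-ratio stretched cardioid models. Orientation is preserved
#' (the determinant of the map is positive).
#'
#' @param p a `seed_polygon`.
#' @param axis `"x"` or `"y"`, the coordinate to stretch.
#' @param factor positive stretch factor; values below 1 compress.
#' @return the elongated `seed_polygon`.
#' @examples
#' ell <- elongate(make_cardioid(1, 720)$polygon, "x", golden_ratio())
#' @export
elongate <- function(p, axis = c("x", "y"), factor) {
  axis <- match.arg(axis)
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor <= 0)
    stop("elongation factor must be a positive scalar", call. = FALSE)
  ctr <- poly_centroid(p)
  if (axis == "x") p$x <- ctr[1] + factor * (p$x - ctr[1])
  else             p$y <- ctr[2] + factor * (p$y - ctr[2])
  p
}

#' Convex hull of a polygon
#'
#' The smallest convex figure containing all vertices; its boundary length
#' is the convex perimeter used by the rugosity index.
#'
#' @param p a `seed_polygon` (>= 3 vertices).
#' @return the hull as a counter-clockwise `seed_polygon` whose vertices are
#'   a subset of the input vertices.
#' @export
convex_hull <- function(p) {
  idx <- grDevices::chull(p$x, p$y)
  if (length(idx) < 3L)
    stop("degenerate region: all points collinear", call. = FALSE)
  # chull returns clockwise order; reverse for CCW
  idx <- rev(idx)
  polygon_xy(p$x[idx], p$y[idx])
}

#' Simplicity check (no self-intersections)
#'
#' Brute-force all-pairs segment intersection test, O(n^2). Adjacent edges
#' sharing a vertex are exempt. Intended for model validation and test
#' oracles, not for hot loops.
#'
#' @param p a `seed_polygon`.
#' @return `TRUE` if no two non-adjacent edges cross or touch.
#' @export
poly_is_simple <- function(p) {
  n <- length(p$x)
  x1 <- p$x; y1 <- p$y
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  ij <- which(outer(seq_len(n), seq_len(n), function(i, j) {
    j > i + 1L & !(i == 1L & j == n)
  }), arr.ind = TRUE)
  i <- ij[, 1]; j <- ij[, 2]
  d1 <- cross2(x2[i] - x1[i], y2[i] - y1[i], x1[j] - x1[i], y1[j] - y1[i])
  d2 <- cross2(x2[i] - x1[i], y2[i] - y1[i], x2[j] - x1[i], y2[j] - y1[i])
  d3 <- cross2(x2[j] - x1[j], y2[j] - y1[j], x1[i] - x1[j], y1[i] - y1[j])
  d4 <- cross2(x2[j] - x1[j], y2[j] - y1[j], x2[i] - x1[j], y2[i] - y1[j])
  !any(d1 * d2 < 0 & d3 * d4 < 0)
}

cross2 <- function(ax, ay, bx, by) ax * by - ay * bx

#' Minimum-area rotated bounding rectangle
#'
#' Rotating-calipers search over convex hull edge directions. Length `L` is
#' the longer rectangle side, width `W` the shorter; this is the caliper
#' convention used by the eccentricity index.
#'
#' @param p a `seed_polygon`.
#' @return list with `length`, `width`, `angle` (radians of the long side).
#' @export
min_area_rect <- function(p) {
  h <- convex_hull(p)
  hx <- h$x; hy <- h$y
  nh <- length(hx)
  ex <- c(hx[-1], hx[1]) - hx
  ey <- c(hy[-1], hy[1]) - hy
  ang <- atan2(ey, ex)
  best <- NULL
  for (a in unique(round(ang %% pi, 12))) {
    ct <- cos(-a); st <- sin(-a)
    rx <- ct * hx - st * hy
    ry <- st * hx + ct * hy
    w1 <- diff(range(rx)); w2 <- diff(range(ry))
    area <- w1 * w2
    if (is.null(best) || area < best$area) {
      long <- max(w1, w2)
      angle <- if (w1 >= w2) a else (a + pi / 2) %% pi
      best <- list(area = area, length = long, width = min(w1, w2),
                   angle = angle)
    }
  }
  best[c("length", "width", "angle")]
}
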
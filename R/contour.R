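# Closed-contour geometry: construction, orientation, resampling, areas and
# point-in-polygon containment. Contour points are real-valued (row, col)
# pixel coordinates; the polygon is implicitly closed.

#' Construct a closed contour
#'
#' @param points Numeric matrix with two columns (row, col); the polygon is
#'   implicitly closed. At least 16 points; must be simple (no
#'   self-intersections) with positive enclosed area. Orientation is
#'   normalised to counter-clockwise.
#' @param check_simple Verify non-self-intersection (O(n^2); skip for trusted
#'   intermediate contours).
#' @return An object of class \code{contour} with elements \code{points} and
#'   \code{n_points}.
#' @export
contour <- function(points, check_simple = TRUE) {
  points <- as.matrix(points)
  if (ncol(points) != 2 || !is.numeric(points) || any(!is.finite(points)))
    stop("contour points must be a finite numeric n x 2 matrix")
  if (nrow(points) < 16) stop("a contour needs at least 16 points")
  a <- polygon_signed_area(points)
  if (abs(a) <= 0) stop("contour must enclose a positive area")
  if (a < 0) points <- points[nrow(points):1, , drop = FALSE]
  if (check_simple && !polygon_is_simple(points))
    stop("contour is self-intersecting")
  structure(list(points = points, n_points = nrow(points)), class = "contour")
}

#' @export
print.contour <- function(x, ...) {
  cat(sprintf("<contour> %d points, area %.1f px^2\n", x$n_points,
              contour_area(x)))
  invisible(x)
}

# Signed area with x = col, y = row; positive is the orientation we call
# counter-clockwise throughout the package.
polygon_signed_area <- function(points) {
  y <- points[, 1]; x <- points[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Enclosed area of a contour in squared pixels
#' @param x A \code{\link{contour}}.
#' @return Absolute shoelace area, px^2.
#' @export
contour_area <- function(x) abs(polygon_signed_area(x$points))

contour_perimeter <- function(x) {
  p <- x$points
  d <- rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE]) - p
  sum(sqrt(rowSums(d^2)))
}

contour_centroid <- function(points) {
  y <- points[, 1]; x <- points[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-9) return(c(mean(y), mean(x)))
  c(sum((y + yn) * cr) / (6 * a), sum((x + xn) * cr) / (6 * a))
}

# Segment self-intersection test, excluding shared-endpoint neighbours.
polygon_is_simple <- function(points) {
  n <- nrow(points)
  p1 <- points
  p2 <- rbind(points[-1, , drop = FALSE], points[1, , drop = FALSE])
  idx <- utils::combn(n, 2)
  i <- idx[1, ]; j <- idx[2, ]
  adj <- (j - i == 1) | (i == 1 & j == n)
  i <- i[!adj]; j <- j[!adj]
  if (length(i) == 0) return(TRUE)
  cross2 <- function(ax, ay, bx, by) ax * by - ay * bx
  ax <- p1[i, 2]; ay <- p1[i, 1]; bx <- p2[i, 2]; by <- p2[i, 1]
  cx <- p1[j, 2]; cy <- p1[j, 1]; dx <- p2[j, 2]; dy <- p2[j, 1]
  d1 <- cross2(bx - ax, by - ay, cx - ax, cy - ay)
  d2 <- cross2(bx - ax, by - ay, dx - ax, dy - ay)
  d3 <- cross2(dx - cx, dy - cy, ax - cx, ay - cy)
  d4 <- cross2(dx - cx, dy - cy, bx - cx, by - cy)
  !any(d1 * d2 < 0 & d3 * d4 < 0)
}

#' Resample a contour to uniformly spaced points along its arc length
#'
#' @param x A \code{\link{contour}} (or raw point matrix).
#' @param n Number of output points.
#' @return A \code{\link{contour}} with \code{n} points.
#' @export
resample_contour <- function(x, n) {
  points <- if (inherits(x, "contour")) x$points else as.matrix(x)
  contour(resample_points(points, n), check_simple = FALSE)
}

resample_points <- function(points, n) {
  closed <- rbind(points, points[1, , drop = FALSE])
  seg <- sqrt(rowSums((closed[-1, , drop = FALSE] -
                       closed[-nrow(closed), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) stop("degenerate contour: zero perimeter")
  target <- seq(0, total, length.out = n + 1)[-(n + 1)]
  cbind(stats::approx(s, closed[, 1], xout = target, ties = "ordered")$y,
        stats::approx(s, closed[, 2], xout = target, ties = "ordered")$y)
}

#' Even-odd point-in-polygon test
#'
#' Vectorised ray-casting with the half-open vertex rule, so each query point
#' gets a definite answer; points numerically on an edge follow the crossing
#' convention and are treated as inside for pixel-membership purposes.
#'
#' @param row,col Numeric vectors of query coordinates.
#' @param points Polygon vertex matrix (row, col), implicitly closed.
#' @return Logical vector.
#' @export
points_in_polygon <- function(row, col, points) {
  py <- points[, 1]; px <- points[, 2]
  pyn <- c(py[-1], py[1]); pxn <- c(px[-1], px[1])
  inside <- logical(length(row))
  for (k in seq_along(py)) {
    y1 <- py[k]; x1 <- px[k]; y2 <- pyn[k]; x2 <- pxn[k]
    if (y1 == y2) next
    crosses <- (y1 > row) != (y2 > row)
    xi <- x1 + (row - y1) * (x2 - x1) / (y2 - y1)
    inside <- xor(inside, crosses & (col <= xi))
  }
  inside
}

#' Rasterise the interior of a contour onto a pixel grid
#'
#' Pixel membership is decided by the pixel centre (integer coordinates).
#'
#' @param x A \code{\link{contour}}.
#' @param nr,nc Grid dimensions.
#' @return Logical nr x nc matrix.
#' @export
contour_mask <- function(x, nr, nc) {
  pts <- x$points
  rr <- max(1L, floor(min(pts[, 1]))):min(nr, ceiling(max(pts[, 1])))
  cc <- max(1L, floor(min(pts[, 2]))):min(nc, ceiling(max(pts[, 2])))
  grid_r <- rep(rr, times = length(cc))
  grid_c <- rep(cc, each = length(rr))
  m <- matrix(FALSE, nr, nc)
  m[cbind(grid_r, grid_c)] <- points_in_polygon(grid_r, grid_c, pts)
  m
}

#' Pair of nested abdominal-wall contours
#'
#' @param outer,inner \code{\link{contour}} objects; every inner vertex must
#'   lie inside or on the outer polygon and the inner area must be smaller.
#' @return An object of class \code{wall_contours}.
#' @export
wall_contours <- function(outer, inner) {
  if (!inherits(outer, "contour") || !inherits(inner, "contour"))
    stop("outer and inner must be contour objects")
  if (!all(points_in_polygon(inner$points[, 1], inner$points[, 2],
                             outer$points)))
    stop("inner contour is not contained in the outer contour")
  if (contour_area(inner) >= contour_area(outer))
    stop("inner contour area must be smaller than the outer contour area")
  structure(list(outer = outer, inner = inner), class = "wall_contours")
}

#' @export
print.wall_contours <- function(x, ...) {
  cat(sprintf("<wall_contours> outer %.1f px^2, inner %.1f px^2\n",
              contour_area(x$outer), contour_area(x$inner)))
  invisible(x)
}
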
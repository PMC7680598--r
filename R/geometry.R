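#' Planar geometry primitives
#'
#' All index constructions reduce to a handful of exact planar operations on
#' calibrated 2D points (millimetres, y increasing distally). Points are plain
#' numeric vectors `c(x, y)`; lines are anchored two-point objects created with
#' [line2d()].
#'
#' @name geometry
NULL

#' Create a point
#'
#' @param x,y Coordinates in millimetres. `y` increases distally (toward the
#'   foot); `x` orientation is free because every derived quantity is a
#'   distance, ratio or unsigned angle.
#' @return A numeric vector `c(x, y)`.
#' @export
#' @examples
#' point2d(14, 11)
point2d <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != 1L || length(y) != 1L)
    stop("point coordinates must be single numeric values", call. = FALSE)
  if (!is.finite(x) || !is.finite(y))
    stop("point coordinates must be finite", call. = FALSE)
  c(x = as.numeric(x), y = as.numeric(y))
}

as_point <- function(p, what = "point") {
  if (!is.numeric(p) || length(p) != 2L || !all(is.finite(p)))
    stop(sprintf("%s must be a finite numeric vector of length 2", what),
         call. = FALSE)
  unname(as.numeric(p))
}

#' Create a line through two distinct points
#'
#' @param p,q Points (`c(x, y)`, millimetres); must be distinct.
#' @return An object of class `line2d` with fields `p`, `q` and the unit
#'   direction `u = (q - p) / |q - p|`.
#' @export
#' @examples
#' line2d(c(0, 70), c(0, 110))  # a vertical shaft axis
line2d <- function(p, q) {
  p <- as_point(p, "p")
  q <- as_point(q, "q")
  d <- q - p
  len <- sqrt(sum(d^2))
  if (len <= 0)
    stop("degenerate line: the two defining points coincide", call. = FALSE)
  structure(list(p = p, q = q, u = d / len, length = len), class = "line2d")
}

is_line2d <- function(x) inherits(x, "line2d")

check_line <- function(l, what = "line") {
  if (!is_line2d(l)) stop(sprintf("%s must be a 'line2d' object", what),
                          call. = FALSE)
  l
}

#' @export
print.line2d <- function(x, ...) {
  cat(sprintf("<line2d> through (%.4g, %.4g) and (%.4g, %.4g)\n",
              x$p[1], x$p[2], x$q[1], x$q[2]))
  invisible(x)
}

#' Euclidean distance between two points
#'
#' @param p1,p2 Points (`c(x, y)`, millimetres).
#' @return Distance in millimetres.
#' @export
#' @examples
#' point_distance(c(-16, -12), c(0, 0))  # 20
point_distance <- function(p1, p2) {
  p1 <- as_point(p1, "p1"); p2 <- as_point(p2, "p2")
  sqrt(sum((p1 - p2)^2))
}

#' Midpoint of two points
#'
#' Used to derive a mid-diaphyseal point from an anterior/posterior cortex
#' pair at a given shaft level.
#'
#' @param p1,p2 Points.
#' @return The midpoint `(p1 + p2) / 2`.
#' @export
midpoint <- function(p1, p2) {
  p1 <- as_point(p1, "p1"); p2 <- as_point(p2, "p2")
  (p1 + p2) / 2
}

#' Orthogonal projection of a point onto a line
#'
#' This is the construction behind the T1 reference point: the foot of the
#' perpendicular from the fibular head tip to the tibial shaft axis.
#'
#' @param pt Point to project.
#' @param l A [line2d()].
#' @return The foot of the perpendicular, a point on `l`.
#' @export
#' @examples
#' project_point(c(14, 11), line2d(c(0, 70), c(0, 110)))  # (0, 11)
project_point <- function(pt, l) {
  pt <- as_point(pt, "pt"); l <- check_line(l)
  t <- sum((pt - l$p) * l$u)
  unname(l$p + t * l$u)
}

#' Intersection of two non-parallel lines
#'
#' The construction behind T2: the intersection of the tibial shaft axis with
#' the joint line. Near-parallel configurations (|sin of angle| below 1e-9)
#' are rejected: the axis and joint line are nearly perpendicular on any
#' plausible radiograph, so near-parallel input indicates corrupt landmarks.
#'
#' @param l1,l2 [line2d()] objects.
#' @return The intersection point.
#' @export
intersect_lines <- function(l1, l2) {
  l1 <- check_line(l1, "l1"); l2 <- check_line(l2, "l2")
  cr <- l1$u[1] * l2$u[2] - l1$u[2] * l2$u[1]
  if (abs(cr) <= 1e-9)
    stop(sprintf(paste0("degenerate geometry: lines are parallel or ",
                        "near-parallel (|sin angle| = %.3g); line 1 through ",
                        "(%.4g, %.4g)-(%.4g, %.4g), line 2 through ",
                        "(%.4g, %.4g)-(%.4g, %.4g)"),
                 abs(cr), l1$p[1], l1$p[2], l1$q[1], l1$q[2],
                 l2$p[1], l2$p[2], l2$q[1], l2$q[2]), call. = FALSE)
  # solve p1 + t * u1 = p2 + s * u2 for t by Cramer's rule
  rhs <- l2$p - l1$p
  t <- (rhs[1] * l2$u[2] - rhs[2] * l2$u[1]) / cr
  unname(l1$p + t * l1$u)
}

#' Perpendicular distance from a point to a line
#'
#' @param pt Point.
#' @param l A [line2d()].
#' @return Distance in millimetres (the Blackburne-Peel numerator
#'   construction).
#' @export
point_line_distance <- function(pt, l) {
  point_distance(as_point(pt, "pt"), project_point(pt, l))
}

#' Unsigned angle between two lines
#'
#' @param l1,l2 [line2d()] objects.
#' @return Angle in degrees in `[0, 90]` (clinical convention; internally
#'   computed in radians).
#' @export
angle_between <- function(l1, l2) {
  l1 <- check_line(l1, "l1"); l2 <- check_line(l2, "l2")
  d <- abs(sum(l1$u * l2$u))
  d <- min(max(d, 0), 1)
  acos(d) * 180 / pi
}
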
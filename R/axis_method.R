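#' Tibial shaft axis
#'
#' The mid-diaphyseal line through the two shaft points nominally 70 and
#' 110 mm distal to the tibial plateau, anchored at the 70 mm point. Points
#' closer than 20 mm give an ill-conditioned direction and are rejected.
#'
#' @param lm A [knee_landmarks()] object (shaft points given directly or
#'   derived from cortex pairs at construction time).
#' @return A [line2d()].
#' @export
tibial_shaft_axis <- function(lm) {
  stopifnot(inherits(lm, "knee_landmarks"))
  p70 <- lm$points$shaft_mid_70
  p110 <- lm$points$shaft_mid_110
  if (is.null(p70) || is.null(p110))
    stop("tibial shaft axis: mid-diaphyseal points absent", call. = FALSE)
  if (point_distance(p70, p110) < 20)
    stop(sprintf(paste0("AXIS_SHORT: mid-diaphyseal points %.1f mm apart; ",
                        "at least 20 mm is required for a stable axis ",
                        "direction"), point_distance(p70, p110)),
         call. = FALSE)
  line2d(p70, p110)
}

#' T1 reference point
#'
#' Intersection of the tibial shaft axis with its perpendicular through the
#' tip of the fibular head, i.e. the orthogonal projection of the fibular tip
#' onto the axis. The fibular head is independent of the arthroplasty, so T1
#' is stable across surgery.
#'
#' @param axis The shaft axis ([line2d()]).
#' @param fibular_head_tip Point `c(x, y)`.
#' @return T1, a point on the axis.
#' @export
locate_T1 <- function(axis, fibular_head_tip) {
  project_point(fibular_head_tip, axis)
}

#' T2 reference point
#'
#' Intersection of the tibial shaft axis with the joint line. T2 shifts along
#' the axis when the joint line moves, which is what makes the jAP index and
#' JLH sensitive to joint-line elevation.
#'
#' @param axis The shaft axis ([line2d()]).
#' @param joint The joint line ([line2d()]).
#' @return T2, the intersection point.
#' @export
locate_T2 <- function(axis, joint) {
  intersect_lines(axis, joint)
}

#' Axis-based indices: AP, jAP and JLH
#'
#' Constructs the tibial shaft axis, T1 (projection of the fibular head tip)
#' and T2 (axis / joint-line intersection), then
#' \itemize{
#'   \item `a1` = distance from the inferior articular pole to T1,
#'   \item `a2` = distance from the inferior articular pole to T2,
#'   \item `b`  = patellar articular surface length,
#'   \item `AP = a1 / b`, `jAP = a2 / b`, `JLH = |T1 - T2|` (mm, unsigned).
#' }
#' `a1` and `a2` are straight Euclidean segments, not along-axis projections.
#' JLH is reported unsigned; the signed along-axis offset of T2 relative to
#' T1 (positive when T2 is proximal to T1) is exposed as `jlh_signed` for
#' verbose output.
#'
#' @param lm A [knee_landmarks()] object.
#' @return An object of class `axis_construction`: `axis`, `T1`, `T2`, `a1`,
#'   `a2`, `b`, `AP`, `jAP`, `JLH`, `jlh_signed`.
#' @export
axis_indices <- function(lm) {
  stopifnot(inherits(lm, "knee_landmarks"))
  need_points(lm, c("articular_inferior_pole", "articular_superior_pole",
                    "fibular_head_tip"), "axis indices")
  axis <- tibial_shaft_axis(lm)
  T1 <- locate_T1(axis, lm$points$fibular_head_tip)
  T2 <- locate_T2(axis, joint_line(lm))
  pole <- lm$points$articular_inferior_pole
  a1 <- point_distance(pole, T1)
  a2 <- point_distance(pole, T2)
  b <- articular_length(lm)
  if (b <= 0)
    stop("axis indices: zero-length articular surface", call. = FALSE)
  jlh <- point_distance(T1, T2)
  # distal axis direction: from the 70 mm level toward the 110 mm level
  signed <- sum((T1 - T2) * axis$u)
  structure(list(axis = axis, T1 = T1, T2 = T2, a1 = a1, a2 = a2, b = b,
                 AP = a1 / b, jAP = a2 / b, JLH = jlh, jlh_signed = signed),
            class = "axis_construction")
}

#' @export
print.axis_construction <- function(x, digits = 4, ...) {
  cat("<axis_construction>\n")
  cat(sprintf("  T1 (%.*f, %.*f)  T2 (%.*f, %.*f)\n",
              digits, x$T1[1], digits, x$T1[2],
              digits, x$T2[1], digits, x$T2[2]))
  cat(sprintf("  a1 %.4f  a2 %.4f  b %.4f mm\n", x$a1, x$a2, x$b))
  cat(sprintf("  AP %.4f  jAP %.4f  JLH %.4f mm (signed %+.4f)\n",
              x$AP, x$jAP, x$JLH, x$jlh_signed))
  invisible(x)
}

#' Pre/post paired differences
#'
#' Differences are post minus pre for every index; a positive JLH difference
#' means proximal elevation of the joint line.
#'
#' @param pre,post `index_panel` objects for the same knee, phases `"pre"`
#'   and `"post"`.
#' @return An object of class `paired_case`: `case_id`, the two panels, and
#'   `deltas` (named numeric vector over IS, mIS, CD, BP, AP, jAP, JLH, PTS).
#' @export
paired_deltas <- function(pre, post) {
  stopifnot(inherits(pre, "index_panel"), inherits(post, "index_panel"))
  if (pre$case_id != post$case_id)
    stop(sprintf("pairing error: case ids differ ('%s' vs '%s')",
                 pre$case_id, post$case_id), call. = FALSE)
  if (pre$phase != "pre" || post$phase != "post")
    stop(sprintf("pairing error: expected phases pre/post, got '%s'/'%s'",
                 pre$phase, post$phase), call. = FALSE)
  deltas <- vapply(PANEL_INDICES,
                   function(nm) post[[nm]] - pre[[nm]], numeric(1))
  structure(list(case_id = pre$case_id, pre = pre, post = post,
                 deltas = deltas),
            class = "paired_case")
}

#' @export
print.paired_case <- function(x, ...) {
  cat(sprintf("<paired_case> case %s; dJLH %+.3f mm, dAP %+.4f, djAP %+.4f\n",
              x$case_id, x$deltas[["JLH"]], x$deltas[["AP"]],
              x$deltas[["jAP"]]))
  invisible(x)
}
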
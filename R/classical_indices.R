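#' Joint line of a radiograph
#'
#' The line through the two joint-line landmarks. Preoperatively these
#' annotate the tibial plateau; postoperatively the tangent of the distal
#' femoral component parallel to the tibial osteotomy plane. The construction
#' is identical in both phases - the phase difference lives entirely in what
#' the annotator clicked.
#'
#' @param lm A [knee_landmarks()] object.
#' @return A [line2d()].
#' @export
joint_line <- function(lm) {
  stopifnot(inherits(lm, "knee_landmarks"))
  line2d(lm$points$joint_line_a, lm$points$joint_line_b)
}

need_points <- function(lm, names, index) {
  for (nm in names)
    if (is.null(lm$points[[nm]]))
      stop(sprintf("%s: required landmark '%s' is absent", index, nm),
           call. = FALSE)
}

ratio_or_degenerate <- function(a, b, index) {
  if (b <= 0)
    stop(sprintf("%s: zero-length denominator segment", index), call. = FALSE)
  a / b
}

#' Insall-Salvati index
#'
#' Patellar tendon length (inferior patellar pole to the tendon insertion on
#' the tibia, a notch superior to the tibial tubercle) over the greatest
#' pole-to-pole patellar length. The tendon is measured as a straight
#' segment.
#'
#' @param lm A [knee_landmarks()] object.
#' @return Dimensionless ratio.
#' @export
insall_salvati <- function(lm) {
  stopifnot(inherits(lm, "knee_landmarks"))
  need_points(lm, c("patella_inferior_pole", "patella_superior_pole",
                    "tendon_insertion"), "Insall-Salvati")
  a <- point_distance(lm$points$patella_inferior_pole,
                      lm$points$tendon_insertion)
  b <- point_distance(lm$points$patella_superior_pole,
                      lm$points$patella_inferior_pole)
  ratio_or_degenerate(a, b, "Insall-Salvati")
}

#' Modified Insall-Salvati index
#'
#' Distance from the inferior pole of the patellar articular surface to the
#' tendon insertion, over the articular surface length.
#'
#' @inheritParams insall_salvati
#' @return Dimensionless ratio.
#' @export
modified_insall_salvati <- function(lm) {
  stopifnot(inherits(lm, "knee_landmarks"))
  need_points(lm, c("articular_inferior_pole", "articular_superior_pole",
                    "tendon_insertion"), "modified Insall-Salvati")
  a <- point_distance(lm$points$articular_inferior_pole,
                      lm$points$tendon_insertion)
  b <- articular_length(lm)
  ratio_or_degenerate(a, b, "modified Insall-Salvati")
}

articular_length <- function(lm) {
  point_distance(lm$points$articular_superior_pole,
                 lm$points$articular_inferior_pole)
}

#' Caton-Deschamps index
#'
#' Distance from the inferior pole of the patellar articular surface to the
#' antero-superior margin of the tibia, over the articular surface length.
#' Postoperatively the margin landmark annotates the implant surface; the
#' bone resection and implant design shift that reference, so pre/post
#' comparability of this index is limited - the index is computed from
#' whatever margin the annotator supplied, without adjustment.
#'
#' A margin coincident with the articular inferior pole gives 0; this is
#' geometrically meaningful (degenerate-low) and is returned, not raised.
#'
#' @inheritParams insall_salvati
#' @return Dimensionless ratio.
#' @export
caton_deschamps <- function(lm) {
  stopifnot(inherits(lm, "knee_landmarks"))
  need_points(lm, c("articular_inferior_pole", "articular_superior_pole",
                    "tibia_anterosuperior_margin"), "Caton-Deschamps")
  a <- point_distance(lm$points$articular_inferior_pole,
                      lm$points$tibia_anterosuperior_margin)
  ratio_or_degenerate(a, articular_length(lm), "Caton-Deschamps")
}

#' Blackburne-Peel index
#'
#' Perpendicular distance from the inferior pole of the patellar articular
#' surface to the joint line, over the articular surface length.
#'
#' @inheritParams insall_salvati
#' @return Dimensionless ratio.
#' @export
blackburne_peel <- function(lm) {
  stopifnot(inherits(lm, "knee_landmarks"))
  need_points(lm, c("articular_inferior_pole", "articular_superior_pole",
                    "joint_line_a", "joint_line_b"), "Blackburne-Peel")
  a <- point_line_distance(lm$points$articular_inferior_pole, joint_line(lm))
  ratio_or_degenerate(a, articular_length(lm), "Blackburne-Peel")
}

#' Posterior tibial slope
#'
#' Angle between the joint line and the normal to the tibial shaft axis,
#' folded into `[0, 90]` degrees: 0 when the plateau is perpendicular to the
#' shaft axis. This is the standard clinical operationalisation of the slope
#' on a lateral radiograph.
#'
#' @inheritParams insall_salvati
#' @return Degrees in `[0, 90]`.
#' @export
posterior_tibial_slope <- function(lm) {
  stopifnot(inherits(lm, "knee_landmarks"))
  ang <- angle_between(joint_line(lm), tibial_shaft_axis(lm))
  90 - ang
}

#' Compute the full index panel for one radiograph
#'
#' The four classical patellar-height indices, the axis-based AP and jAP
#' indices, the joint line height (JLH, mm) and the posterior tibial slope
#' (PTS, degrees).
#'
#' @param lm A [knee_landmarks()] object.
#' @return An object of class `index_panel` with fields `case_id`, `side`,
#'   `phase`, `IS`, `mIS`, `CD`, `BP`, `AP`, `jAP`, `JLH`, `PTS`, and the
#'   underlying `construction` ([axis_indices()] output).
#' @export
#' @examples
#' lm <- generate_knee(knee_anatomy(plateau_slope_deg = 0))
#' compute_panel(lm)
compute_panel <- function(lm) {
  stopifnot(inherits(lm, "knee_landmarks"))
  wrap <- function(index, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("panel for case %s: %s failed: %s",
                   lm$case_id, index, conditionMessage(e)), call. = FALSE))
  }
  ax <- wrap("axis indices", axis_indices(lm))
  structure(list(case_id = lm$case_id, side = lm$side, phase = lm$phase,
                 IS  = wrap("IS",  insall_salvati(lm)),
                 mIS = wrap("mIS", modified_insall_salvati(lm)),
                 CD  = wrap("CD",  caton_deschamps(lm)),
                 BP  = wrap("BP",  blackburne_peel(lm)),
                 AP  = ax$AP, jAP = ax$jAP, JLH = ax$JLH,
                 PTS = wrap("PTS", posterior_tibial_slope(lm)),
                 construction = ax),
            class = "index_panel")
}

PANEL_INDICES <- c("IS", "mIS", "CD", "BP", "AP", "jAP", "JLH", "PTS")

#' @export
print.index_panel <- function(x, digits = 4, ...) {
  cat(sprintf("<index_panel> case %s (%s, %s)\n", x$case_id, x$side, x$phase))
  v <- vapply(PANEL_INDICES, function(nm) x[[nm]], numeric(1))
  lab <- sprintf("%s %s", PANEL_INDICES,
                 ifelse(PANEL_INDICES == "JLH", "mm",
                        ifelse(PANEL_INDICES == "PTS", "deg", "")))
  cat(paste(sprintf("  %-8s %.*f", trimws(lab), digits, v), collapse = "\n"),
      "\n")
  invisible(x)
}

#' Panel collection as a data frame
#'
#' @param panels A list of `index_panel` objects (or a single one).
#' @return Data frame with columns `case_id`, `side`, `phase`, `IS`, `mIS`,
#'   `CD`, `BP`, `AP`, `jAP`, `JLH_mm`, `PTS_deg`.
#' @export
panel_table <- function(panels) {
  if (inherits(panels, "index_panel")) panels <- list(panels)
  do.call(rbind, lapply(panels, function(p)
    data.frame(case_id = p$case_id, side = p$side, phase = p$phase,
               IS = p$IS, mIS = p$mIS, CD = p$CD, BP = p$BP,
               AP = p$AP, jAP = p$jAP, JLH_mm = p$JLH, PTS_deg = p$PTS)))
}
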
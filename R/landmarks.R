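LANDMARK_SCHEMA_VERSION <- "1.0"

# Landmarks every radiograph must carry. tibia_anterosuperior_margin is
# required preoperatively (Caton-Deschamps reference); postoperatively the
# same field holds the implant-surface margin the annotator supplied.
LANDMARK_NAMES <- c(
  "patella_superior_pole", "patella_inferior_pole",
  "articular_superior_pole", "articular_inferior_pole",
  "tendon_insertion", "tibia_anterosuperior_margin",
  "joint_line_a", "joint_line_b",
  "fibular_head_tip", "shaft_mid_70", "shaft_mid_110"
)

QC_CODES <- c("LOW_FLEXION", "MISSING_LANDMARK", "AXIS_SHORT",
              "OFFSET_OUT_OF_SPEC", "UNIT_SUSPECT")

#' Construct a calibrated knee landmark set
#'
#' One object per lateral radiograph: the named landmarks of the classical
#' patellar-height constructions and of the tibial-shaft-axis method, plus
#' phase and calibration metadata. Coordinates are planar millimetres with y
#' increasing distally; orientation of x is free.
#'
#' @param case_id Opaque case identifier.
#' @param side `"left"` or `"right"` (reporting metadata only).
#' @param phase `"pre"` or `"post"` (which anatomical feature the joint-line
#'   points annotate: tibial plateau preoperatively, tangent of the distal
#'   femoral component parallel to the tibial osteotomy plane
#'   postoperatively).
#' @param points Named list of `c(x, y)` points in millimetres. Required
#'   names: patella_superior_pole, patella_inferior_pole,
#'   articular_superior_pole, articular_inferior_pole, tendon_insertion,
#'   joint_line_a, joint_line_b, fibular_head_tip, shaft_mid_70,
#'   shaft_mid_110; tibia_anterosuperior_margin is required when
#'   `phase = "pre"`. The two shaft points may instead be derived from
#'   `cortex_pairs`.
#' @param flexion_deg Optional knee flexion at acquisition, degrees. Values
#'   below 30 are flagged by [validate_landmarks()] (radiographs in less
#'   flexion do not tension the patellar tendon reproducibly).
#' @param mm_per_pixel Calibration already applied to `points` (1 when the
#'   coordinates were supplied in millimetres).
#' @param cortex_pairs Optional list with elements `"70"` and/or `"110"`,
#'   each `list(anterior =, posterior =)` cortex points from which the
#'   mid-diaphyseal point at that level is derived as the cortex midpoint.
#' @return An object of class `knee_landmarks`.
#' @seealso [read_landmarks()], [validate_landmarks()], [compute_panel()]
#' @export
knee_landmarks <- function(case_id, side = c("left", "right"),
                           phase = c("pre", "post"), points,
                           flexion_deg = NULL, mm_per_pixel = 1,
                           cortex_pairs = NULL) {
  side <- match.arg(side)
  phase <- match.arg(phase)
  if (!is.list(points) || is.null(names(points)))
    stop("'points' must be a named list of c(x, y) coordinates", call. = FALSE)
  if (!is.numeric(mm_per_pixel) || length(mm_per_pixel) != 1L ||
      !is.finite(mm_per_pixel) || mm_per_pixel <= 0)
    stop("'mm_per_pixel' must be a single positive number", call. = FALSE)
  if (!is.null(flexion_deg)) {
    if (!is.numeric(flexion_deg) || length(flexion_deg) != 1L)
      stop("'flexion_deg' must be a single number", call. = FALSE)
    flexion_deg <- as.numeric(flexion_deg)
  }

  # derive mid-diaphyseal points from cortex pairs when not given directly
  if (!is.null(cortex_pairs)) {
    for (lev in c("70", "110")) {
      nm <- paste0("shaft_mid_", lev)
      if (is.null(points[[nm]]) && !is.null(cortex_pairs[[lev]])) {
        cp <- cortex_pairs[[lev]]
        if (is.null(cp$anterior) || is.null(cp$posterior))
          stop(sprintf("cortex pair at level %s needs 'anterior' and 'posterior'",
                       lev), call. = FALSE)
        points[[nm]] <- midpoint(cp$anterior, cp$posterior)
      }
    }
  }

  required <- LANDMARK_NAMES
  if (phase == "post")
    required <- setdiff(required, "tibia_anterosuperior_margin")
  missing <- setdiff(required, names(points))
  if (length(missing))
    stop(sprintf("missing required landmark(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)

  pts <- lapply(points[intersect(LANDMARK_NAMES, names(points))],
                function(p) as_point(p, "landmark"))

  stopifnot_distinct <- function(a, b) {
    if (point_distance(pts[[a]], pts[[b]]) == 0)
      stop(sprintf("landmarks '%s' and '%s' coincide", a, b), call. = FALSE)
  }
  stopifnot_distinct("patella_superior_pole", "patella_inferior_pole")
  stopifnot_distinct("articular_superior_pole", "articular_inferior_pole")
  stopifnot_distinct("joint_line_a", "joint_line_b")
  stopifnot_distinct("shaft_mid_70", "shaft_mid_110")

  structure(list(case_id = as.character(case_id), side = side, phase = phase,
                 flexion_deg = flexion_deg, mm_per_pixel = mm_per_pixel,
                 points = pts),
            class = "knee_landmarks")
}

#' @export
print.knee_landmarks <- function(x, ...) {
  cat(sprintf("<knee_landmarks> case %s, %s knee, phase %s (%d landmarks)\n",
              x$case_id, x$side, x$phase, length(x$points)))
  if (!is.null(x$flexion_deg))
    cat(sprintf("  flexion: %g deg\n", x$flexion_deg))
  invisible(x)
}

#' Read a landmark annotation file
#'
#' Reads one radiograph's landmark JSON file. Pixel coordinates are converted
#' to millimetres by the file's `mm_per_pixel` factor; the returned set is
#' always in millimetres.
#'
#' @param path Path to a landmark JSON file (see [write_landmarks()] for the
#'   schema).
#' @return A [knee_landmarks()] object in millimetres.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path))
    stop(sprintf("landmark file does not exist: %s", path), call. = FALSE)
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (key in c("case_id", "side", "phase", "mm_per_pixel", "points"))
    if (is.null(j[[key]]))
      stop(sprintf("landmark file %s: missing required key '%s'", path, key),
           call. = FALSE)
  scale <- j$mm_per_pixel
  if (!is.numeric(scale) || length(scale) != 1L)
    stop(sprintf("landmark file %s: 'mm_per_pixel' must be numeric", path),
         call. = FALSE)
  to_mm <- function(p, name) {
    p <- unlist(p)
    if (length(p) != 2L || !is.numeric(p) || !all(is.finite(p)))
      stop(sprintf("landmark file %s: non-numeric coordinate for '%s'",
                   path, name), call. = FALSE)
    unname(p * scale)
  }
  pts <- mapply(to_mm, j$points, names(j$points), SIMPLIFY = FALSE)
  cps <- NULL
  if (!is.null(j$cortex_pairs)) {
    cps <- lapply(j$cortex_pairs, function(cp)
      list(anterior = to_mm(cp$anterior, "cortex anterior"),
           posterior = to_mm(cp$posterior, "cortex posterior")))
  }
  knee_landmarks(case_id = j$case_id, side = j$side, phase = j$phase,
                 points = pts,
                 flexion_deg = if (is.null(j$flexion_deg)) NULL else
                   as.numeric(j$flexion_deg),
                 mm_per_pixel = 1,  # coordinates now in mm
                 cortex_pairs = cps)
}

#' Write a landmark annotation file
#'
#' Emits the JSON schema that [read_landmarks()] inverts: top-level keys
#' `schema_version`, `case_id`, `side`, `phase`, optional `flexion_deg`,
#' `mm_per_pixel`, and `points` mapping landmark name to `[x, y]`. Key order
#' is fixed so repeated writes of the same set are byte-identical.
#'
#' @param lm A [knee_landmarks()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(inherits(lm, "knee_landmarks"))
  out <- list(schema_version = LANDMARK_SCHEMA_VERSION,
              case_id = lm$case_id, side = lm$side, phase = lm$phase)
  if (!is.null(lm$flexion_deg)) out$flexion_deg <- lm$flexion_deg
  out$mm_per_pixel <- 1  # sets are stored mm-normalised
  nm <- intersect(LANDMARK_NAMES, names(lm$points))
  out$points <- lapply(lm$points[nm], function(p) unname(p))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Validate a landmark set and produce a QC report
#'
#' QC is advisory: clinically odd geometry yields flags, never errors
#' (exclusion decisions belong at cohort level). Flags:
#' \describe{
#'   \item{LOW_FLEXION}{`flexion_deg` present and below 30 degrees.}
#'   \item{AXIS_SHORT}{mid-diaphyseal points closer than 20 mm; the shaft
#'     axis direction is ill-conditioned.}
#'   \item{OFFSET_OUT_OF_SPEC}{perpendicular distance from a shaft point to
#'     the joint line differs from its nominal 70 / 110 mm level by more than
#'     `offset_tol_mm` (observers place these levels approximately).}
#'   \item{UNIT_SUSPECT}{patellar articular length outside 10-60 mm,
#'     suggesting a pixel/millimetre calibration mix-up.}
#'   \item{MISSING_LANDMARK}{an expected landmark for the declared phase is
#'     absent (only reachable on hand-built lists).}
#' }
#'
#' Osteophytes are excluded at annotation time by the human observer; no
#' automated check can recover that decision and none is attempted.
#'
#' @param lm A [knee_landmarks()] object.
#' @param offset_tol_mm Tolerance on the 70/110 mm shaft-level offsets
#'   (default 15).
#' @return An object of class `qc_report`: `case_id` plus a data frame of
#'   flags (`code`, `severity`, `message`).
#' @export
validate_landmarks <- function(lm, offset_tol_mm = 15) {
  stopifnot(inherits(lm, "knee_landmarks"))
  flags <- list()
  add <- function(code, severity, message) {
    flags[[length(flags) + 1L]] <<- data.frame(code = code,
                                               severity = severity,
                                               message = message)
  }

  required <- LANDMARK_NAMES
  if (lm$phase == "post")
    required <- setdiff(required, "tibia_anterosuperior_margin")
  for (nm in setdiff(required, names(lm$points)))
    add("MISSING_LANDMARK", "error", sprintf("landmark '%s' absent", nm))

  if (!is.null(lm$flexion_deg) && lm$flexion_deg < 30)
    add("LOW_FLEXION", "warning",
        sprintf("knee flexion %g deg is below the 30 deg acquisition minimum",
                lm$flexion_deg))

  p <- lm$points
  if (!is.null(p$shaft_mid_70) && !is.null(p$shaft_mid_110)) {
    axlen <- point_distance(p$shaft_mid_70, p$shaft_mid_110)
    if (axlen < 20)
      add("AXIS_SHORT", "error",
          sprintf("mid-diaphyseal points only %.1f mm apart (need >= 20)",
                  axlen))
    if (!is.null(p$joint_line_a) && !is.null(p$joint_line_b) &&
        point_distance(p$joint_line_a, p$joint_line_b) > 0) {
      jl <- line2d(p$joint_line_a, p$joint_line_b)
      for (spec in list(c("shaft_mid_70", 70), c("shaft_mid_110", 110))) {
        nominal <- as.numeric(spec[2])
        d <- point_line_distance(p[[spec[1]]], jl)
        if (abs(d - nominal) > offset_tol_mm)
          add("OFFSET_OUT_OF_SPEC", "warning",
              sprintf("%s is %.1f mm from the joint line (nominal %g +/- %g)",
                      spec[1], d, nominal, offset_tol_mm))
      }
    }
  }

  if (!is.null(p$articular_superior_pole) && !is.null(p$articular_inferior_pole)) {
    b <- point_distance(p$articular_superior_pole, p$articular_inferior_pole)
    if (b < 10 || b > 60)
      add("UNIT_SUSPECT", "warning",
          sprintf("articular surface length %.2f mm is outside 10-60 mm; check calibration", b))
  }

  flags <- if (length(flags)) do.call(rbind, flags) else
    data.frame(code = character(), severity = character(),
               message = character())
  structure(list(case_id = lm$case_id, flags = flags), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> case %s: %d flag(s)\n", x$case_id, nrow(x$flags)))
  if (nrow(x$flags))
    for (i in seq_len(nrow(x$flags)))
      cat(sprintf("  [%s/%s] %s\n", x$flags$code[i], x$flags$severity[i],
                  x$flags$message[i]))
  invisible(x)
}

#' Read a cohort table of landmark coordinates
#'
#' One row per radiograph: `case_id`, `side`, `phase`, optional
#' `flexion_deg`, then one `<name>_x` / `<name>_y` column pair per landmark,
#' in millimetres.
#'
#' @param path CSV path.
#' @return List of [knee_landmarks()] objects.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (key in c("case_id", "side", "phase"))
    if (!key %in% names(df))
      stop(sprintf("cohort table %s: missing column '%s'", path, key),
           call. = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, , drop = FALSE]
    pts <- list()
    for (nm in LANDMARK_NAMES) {
      cx <- paste0(nm, "_x"); cy <- paste0(nm, "_y")
      if (cx %in% names(df) && cy %in% names(df) &&
          is.finite(row[[cx]]) && is.finite(row[[cy]]))
        pts[[nm]] <- c(row[[cx]], row[[cy]])
    }
    knee_landmarks(case_id = row$case_id, side = row$side, phase = row$phase,
                   points = pts,
                   flexion_deg = if ("flexion_deg" %in% names(df) &&
                                     is.finite(row$flexion_deg))
                     row$flexion_deg else NULL,
                   mm_per_pixel = 1)
  })
}

#' Write a cohort table of landmark coordinates
#'
#' @param lms List of [knee_landmarks()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(lms, path) {
  rows <- lapply(lms, function(lm) {
    row <- data.frame(case_id = lm$case_id, side = lm$side, phase = lm$phase,
                      flexion_deg = if (is.null(lm$flexion_deg)) NA_real_ else
                        lm$flexion_deg)
    for (nm in LANDMARK_NAMES) {
      p <- lm$points[[nm]]
      row[[paste0(nm, "_x")]] <- if (is.null(p)) NA_real_ else p[1]
      row[[paste0(nm, "_y")]] <- if (is.null(p)) NA_real_ else p[2]
    }
    row
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
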
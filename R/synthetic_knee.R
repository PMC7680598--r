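#' Anatomy parameters for the synthetic knee generator
#'
#' A parametric lateral-knee landmark constellation: straight vertical tibial
#' shaft axis, a joint line with a chosen posterior slope crossing the axis
#' at T2 (the origin), the patella suspended proximal to the joint line and
#' the fibular head at a fixed offset from T2. Defaults are centred on a
#' plausible arthritic pre-arthroplasty knee (articular surface ~28 mm,
#' patella ~40 mm, tendon ~40 mm, slope ~9 degrees, JLH ~11 mm).
#'
#' @param articular_length_b Patellar articular surface length, mm.
#' @param patella_length Pole-to-pole bony patellar length, mm.
#' @param tendon_length Patellar tendon length (inferior pole to tibial
#'   insertion), mm.
#' @param plateau_slope_deg Posterior tibial slope, degrees in `[0, 20]`
#'   (posterior side of the plateau more distal).
#' @param fibular_tip_offset Offset `c(posterior, distal)` of the fibular
#'   head tip relative to T2, mm. The distal component equals the noise-free
#'   preoperative JLH.
#' @param margin_offset Distal offset of the antero-superior tibial margin
#'   from the joint line, mm.
#' @param patella_anterior_offset Anterior (horizontal) distance of the
#'   inferior articular pole from the shaft axis, mm.
#' @param patella_proximal_height Perpendicular height of the inferior
#'   articular pole above the joint line, mm.
#' @return An object of class `knee_anatomy`.
#' @export
knee_anatomy <- function(articular_length_b = 28, patella_length = 40,
                         tendon_length = 40, plateau_slope_deg = 9,
                         fibular_tip_offset = c(posterior = 14, distal = 10.9),
                         margin_offset = 2, patella_anterior_offset = 16,
                         patella_proximal_height = 22) {
  a <- list(articular_length_b = articular_length_b,
            patella_length = patella_length, tendon_length = tendon_length,
            plateau_slope_deg = plateau_slope_deg,
            fibular_tip_offset = unname(fibular_tip_offset),
            margin_offset = margin_offset,
            patella_anterior_offset = patella_anterior_offset,
            patella_proximal_height = patella_proximal_height)
  for (nm in c("articular_length_b", "patella_length", "tendon_length"))
    if (a[[nm]] <= 0) stop(sprintf("'%s' must be positive", nm),
                           call. = FALSE)
  if (a$plateau_slope_deg < 0 || a$plateau_slope_deg > 20)
    stop("'plateau_slope_deg' must lie in [0, 20]", call. = FALSE)
  if (length(a$fibular_tip_offset) != 2L)
    stop("'fibular_tip_offset' must be c(posterior, distal)", call. = FALSE)
  structure(a, class = "knee_anatomy")
}

#' Surgery parameters
#'
#' The two causal mechanisms of postoperative patella baja, applied
#' independently: proximal elevation of the joint line (pseudo baja
#' mechanism) and shortening of the patellar tendon (true baja mechanism).
#'
#' @param joint_line_shift_mm Signed shift of the joint line along the shaft
#'   axis; positive = proximal elevation.
#' @param tendon_shortening_frac Fraction in `[0, 0.5)` by which the tendon
#'   shortens, pulling the patella distally along the tendon direction.
#' @return An object of class `surgery_params`.
#' @export
surgery_params <- function(joint_line_shift_mm = 0,
                           tendon_shortening_frac = 0) {
  if (!is.finite(joint_line_shift_mm))
    stop("'joint_line_shift_mm' must be finite", call. = FALSE)
  if (tendon_shortening_frac < 0 || tendon_shortening_frac >= 0.5)
    stop("'tendon_shortening_frac' must lie in [0, 0.5)", call. = FALSE)
  structure(list(joint_line_shift_mm = joint_line_shift_mm,
                 tendon_shortening_frac = tendon_shortening_frac),
            class = "surgery_params")
}

#' Observer noise model
#'
#' Isotropic Gaussian annotation noise, independent across landmarks, plus
#' an optional systematic per-rater bias. Perturbations are keyed by
#' (seed, case, phase, rater, landmark), so repeated observations of the
#' same radiograph by the same rater reproduce exactly while raters, repeats
#' and radiographs stay mutually independent.
#'
#' @param sigma_mm Per-coordinate Gaussian SD in mm (>= 0). The default,
#'   0.5 mm, is a realistic point-and-click precision on a calibrated
#'   radiograph.
#' @param rater_bias Optional named list: rater -> either a single `c(dx,
#'   dy)` offset applied to every landmark, or a named list of per-landmark
#'   offsets.
#' @param seed Integer seed of the noise stream.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma_mm = 0.5, rater_bias = NULL, seed = 1) {
  if (sigma_mm < 0) stop("'sigma_mm' must be >= 0", call. = FALSE)
  structure(list(sigma_mm = sigma_mm, rater_bias = rater_bias,
                 seed = as.integer(seed)),
            class = "noise_model")
}

# deterministic string hash (djb2 variant reduced mod a prime < 2^31),
# used to derive independent per-landmark RNG substreams
stable_hash <- function(...) {
  s <- paste(c(...), collapse = "\r")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483629
  as.integer(h)
}

#' Generate one noise-free preoperative landmark set
#'
#' Places every landmark exactly on the parametric anatomy: T2 at the
#' origin, vertical shaft axis, mid-diaphyseal points at perpendicular
#' distances of exactly 70 and 110 mm from the joint line. The construction
#' is deterministic; noise is added separately by [observe_landmarks()].
#'
#' The bony patellar poles are drawn 2 mm anterior and 2 mm beyond the
#' articular poles (fixed construction constants); the patellar long axis is
#' parallel to the shaft axis and the tendon runs straight distally from the
#' inferior pole to its tibial insertion.
#'
#' @param anat A [knee_anatomy()] object.
#' @param case_id,side Metadata for the generated set.
#' @param flexion_deg Optional recorded flexion angle.
#' @return A [knee_landmarks()] object, `phase = "pre"`.
#' @export
generate_knee <- function(anat = knee_anatomy(), case_id = "synthetic",
                          side = "left", flexion_deg = NULL) {
  stopifnot(inherits(anat, "knee_anatomy"))
  if (anat$patella_proximal_height < -anat$patella_length)
    stop(sprintf(paste0("infeasible anatomy: the inferior articular pole ",
                        "lies %.1f mm distal to the joint line, more than ",
                        "the patellar length (%.1f mm)"),
                 -anat$patella_proximal_height, anat$patella_length),
         call. = FALSE)
  th <- anat$plateau_slope_deg * pi / 180
  tanth <- tan(th); costh <- cos(th); sinth <- sin(th)
  yj <- function(x) x * tanth          # joint line through T2 = (0, 0)
  nhat <- c(-sinth, costh)             # joint-line normal, pointing distal

  p <- anat$patella_proximal_height
  art_inf <- c(-anat$patella_anterior_offset,
               yj(-anat$patella_anterior_offset)) - p * nhat
  art_sup <- art_inf - c(0, anat$articular_length_b)
  pat_inf <- art_inf + c(-2, 2)
  pat_sup <- pat_inf - c(0, anat$patella_length)
  insertion <- pat_inf + c(0, anat$tendon_length)
  margin <- c(art_inf[1], yj(art_inf[1])) + anat$margin_offset * nhat

  pts <- list(
    patella_superior_pole = pat_sup, patella_inferior_pole = pat_inf,
    articular_superior_pole = art_sup, articular_inferior_pole = art_inf,
    tendon_insertion = insertion, tibia_anterosuperior_margin = margin,
    joint_line_a = c(-20, yj(-20)), joint_line_b = c(20, yj(20)),
    fibular_head_tip = c(anat$fibular_tip_offset[1],
                         anat$fibular_tip_offset[2]),
    shaft_mid_70 = c(0, 70 / costh), shaft_mid_110 = c(0, 110 / costh))

  knee_landmarks(case_id = case_id, side = side, phase = "pre", points = pts,
                 flexion_deg = flexion_deg, mm_per_pixel = 1)
}

#' Apply a simulated arthroplasty to a preoperative landmark set
#'
#' The joint-line landmarks (and the margin landmark, which after surgery
#' annotates the implant surface) are translated proximally along the shaft
#' axis by the joint-line shift; tendon shortening translates the whole
#' patella (bony and articular poles) distally along the tendon direction by
#' the shortening fraction of the tendon length. Shaft, fibular and
#' tendon-insertion landmarks are untouched.
#'
#' @param lm Preoperative [knee_landmarks()] object.
#' @param surgery A [surgery_params()] object.
#' @return A [knee_landmarks()] object, `phase = "post"`.
#' @export
apply_surgery <- function(lm, surgery) {
  stopifnot(inherits(lm, "knee_landmarks"), inherits(surgery, "surgery_params"))
  if (lm$phase != "pre")
    stop("apply_surgery expects a preoperative landmark set", call. = FALSE)
  pts <- lm$points
  axis <- tibial_shaft_axis(lm)
  u_distal <- axis$u * sign(sum(axis$u * (pts$shaft_mid_110 - pts$shaft_mid_70)))
  shift_vec <- -surgery$joint_line_shift_mm * u_distal
  for (nm in c("joint_line_a", "joint_line_b", "tibia_anterosuperior_margin"))
    if (!is.null(pts[[nm]])) pts[[nm]] <- pts[[nm]] + shift_vec

  if (surgery$tendon_shortening_frac > 0) {
    tendon <- pts$tendon_insertion - pts$patella_inferior_pole
    tlen <- sqrt(sum(tendon^2))
    drop_vec <- surgery$tendon_shortening_frac * tlen * (tendon / tlen)
    for (nm in c("patella_superior_pole", "patella_inferior_pole",
                 "articular_superior_pole", "articular_inferior_pole"))
      pts[[nm]] <- pts[[nm]] + drop_vec
  }

  knee_landmarks(case_id = lm$case_id, side = lm$side, phase = "post",
                 points = pts, flexion_deg = lm$flexion_deg, mm_per_pixel = 1)
}

#' Observe a landmark set with annotation noise
#'
#' Each landmark is perturbed independently by isotropic Gaussian noise and
#' the rater's systematic bias, with a deterministic per-landmark stream
#' keyed on (seed, case, phase, rater, landmark). The caller's RNG state is
#' left untouched.
#'
#' @param lm A [knee_landmarks()] object.
#' @param noise A [noise_model()] object.
#' @param rater Rater label, part of the noise key.
#' @return A perturbed [knee_landmarks()] object.
#' @export
observe_landmarks <- function(lm, noise, rater = "obs1") {
  stopifnot(inherits(lm, "knee_landmarks"), inherits(noise, "noise_model"))
  bias_for <- function(name) {
    b <- noise$rater_bias[[rater]]
    if (is.null(b)) return(c(0, 0))
    if (is.list(b)) {
      bb <- b[[name]]
      if (is.null(bb)) c(0, 0) else bb
    } else b
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(),
                       inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  pts <- lm$points
  for (nm in names(pts)) {
    e <- c(0, 0)
    if (noise$sigma_mm > 0) {
      set.seed(stable_hash(noise$seed, lm$case_id, lm$phase, rater, nm))
      e <- stats::rnorm(2, 0, noise$sigma_mm)
    }
    pts[[nm]] <- pts[[nm]] + e + bias_for(nm)
  }
  knee_landmarks(case_id = lm$case_id, side = lm$side, phase = lm$phase,
                 points = pts, flexion_deg = lm$flexion_deg, mm_per_pixel = 1)
}

#' Dispersion of the anatomy draws in cohort simulation
#'
#' Per-parameter Gaussian SDs around the [knee_anatomy()] means. Defaults
#' produce index spreads comparable to an arthroplasty cohort (AP SD near
#' 0.17, JLH SD near 3 mm).
#'
#' @param articular_length_b,patella_length,tendon_length,plateau_slope_deg
#'   SDs of the corresponding anatomy parameters.
#' @param fibular_posterior,fibular_distal SDs of the fibular tip offset
#'   components.
#' @param margin_offset,patella_anterior_offset,patella_proximal_height SDs
#'   of the remaining parameters.
#' @return A named list of SDs.
#' @export
anatomy_variation <- function(articular_length_b = 2, patella_length = 3,
                              tendon_length = 3, plateau_slope_deg = 3,
                              fibular_posterior = 2, fibular_distal = 3,
                              margin_offset = 1, patella_anterior_offset = 2,
                              patella_proximal_height = 3) {
  list(articular_length_b = articular_length_b,
       patella_length = patella_length, tendon_length = tendon_length,
       plateau_slope_deg = plateau_slope_deg,
       fibular_posterior = fibular_posterior,
       fibular_distal = fibular_distal, margin_offset = margin_offset,
       patella_anterior_offset = patella_anterior_offset,
       patella_proximal_height = patella_proximal_height)
}

draw_anatomy <- function(mean_anat, sds) {
  rn <- function(m, s) stats::rnorm(1, m, s)
  tries <- 0
  repeat {
    tries <- tries + 1
    a <- try(knee_anatomy(
      articular_length_b = rn(mean_anat$articular_length_b,
                              sds$articular_length_b),
      patella_length = rn(mean_anat$patella_length, sds$patella_length),
      tendon_length = rn(mean_anat$tendon_length, sds$tendon_length),
      plateau_slope_deg = min(max(rn(mean_anat$plateau_slope_deg,
                                     sds$plateau_slope_deg), 0), 20),
      fibular_tip_offset = c(rn(mean_anat$fibular_tip_offset[1],
                                sds$fibular_posterior),
                             rn(mean_anat$fibular_tip_offset[2],
                                sds$fibular_distal)),
      margin_offset = rn(mean_anat$margin_offset, sds$margin_offset),
      patella_anterior_offset = rn(mean_anat$patella_anterior_offset,
                                   sds$patella_anterior_offset),
      patella_proximal_height = rn(mean_anat$patella_proximal_height,
                                   sds$patella_proximal_height)),
      silent = TRUE)
    if (!inherits(a, "try-error")) return(list(anat = a, rejected = tries - 1))
    if (tries > 100)
      stop("anatomy distribution rejects every draw; check its parameters",
           call. = FALSE)
  }
}

#' Generate a paired pre/post cohort with known ground truth
#'
#' Draws `n` knees from the anatomy distributions, applies per-knee surgery
#' draws (joint-line elevation, default Normal(3.17, 3.06) mm; tendon
#' shortening, default none), and produces per-rater observed copies under
#' the noise model. Infeasible draws are rejected and resampled with a
#' logged count; more than 50% rejection aborts.
#'
#' @param n Number of knees.
#' @param anatomy Mean anatomy ([knee_anatomy()]).
#' @param anatomy_sd Anatomy dispersion ([anatomy_variation()]).
#' @param elevation_mean,elevation_sd Normal distribution of the joint-line
#'   shift in mm (draws may be negative: joint-line lowering).
#' @param shortening_mean,shortening_sd Normal distribution of the tendon
#'   shortening fraction, truncated to `[0, 0.5)`.
#' @param noise A [noise_model()]; `NULL` defaults to sigma 0.5 mm with the
#'   cohort seed.
#' @param raters Rater labels for the observed copies. The default emulates
#'   a two-observer protocol with a repeat reading by observer 1.
#' @param seed Integer seed for all draws.
#' @return An object of class `knee_cohort`:
#'   \describe{
#'     \item{cases}{list per knee: `pre`, `post` (noise-free landmark sets),
#'       `observed` (rater -> list(pre, post)).}
#'     \item{ground_truth}{data frame of drawn parameters and noise-free
#'       index panels (columns `pre_*`, `post_*`, `joint_line_shift_mm`,
#'       `tendon_shortening_frac`).}
#'     \item{ratings}{long data frame `subject_id` (case x phase), `rater`,
#'       one column per index, from the observed copies.}
#'     \item{params}{resolved generation parameters (the manifest).}
#'     \item{n_rejected}{count of infeasible anatomy/surgery draws.}
#'   }
#' @export
generate_cohort <- function(n, anatomy = knee_anatomy(),
                            anatomy_sd = anatomy_variation(),
                            elevation_mean = 3.17, elevation_sd = 3.06,
                            shortening_mean = 0, shortening_sd = 0,
                            noise = NULL,
                            raters = c("obs1a", "obs1b", "obs2"),
                            seed = 1) {
  if (n < 1) stop("'n' must be at least 1", call. = FALSE)
  if (is.null(noise)) noise <- noise_model(sigma_mm = 0.5, seed = seed)
  set.seed(seed)
  cases <- vector("list", n)
  truth <- vector("list", n)
  ratings <- list()
  rejected <- 0L

  for (i in seq_len(n)) {
    case_id <- sprintf("case_%04d", i)
    side <- sample(c("left", "right"), 1)
    repeat {
      da <- draw_anatomy(anatomy, anatomy_sd)
      rejected <- rejected + da$rejected
      shift <- stats::rnorm(1, elevation_mean, elevation_sd)
      short <- if (shortening_sd > 0 || shortening_mean > 0)
        min(max(stats::rnorm(1, shortening_mean, shortening_sd), 0), 0.499)
      else 0
      # physical feasibility: the elevated joint line must not overrun the
      # whole patella
      if (shift >= da$anat$patella_proximal_height + da$anat$patella_length) {
        rejected <- rejected + 1L
        if (rejected > 10 * n)
          stop("more than 50% of surgery draws are infeasible; check the elevation distribution", call. = FALSE)
        next
      }
      pre <- generate_knee(da$anat, case_id = case_id, side = side)
      post <- apply_surgery(pre, surgery_params(shift, short))
      break
    }

    observed <- lapply(raters, function(r)
      list(pre = observe_landmarks(pre, noise, r),
           post = observe_landmarks(post, noise, r)))
    names(observed) <- raters
    cases[[i]] <- list(case_id = case_id, pre = pre, post = post,
                       observed = observed)

    pp <- compute_panel(pre); qp <- compute_panel(post)
    tr <- data.frame(case_id = case_id, side = side,
                     joint_line_shift_mm = shift,
                     tendon_shortening_frac = short)
    for (nm in PANEL_INDICES) {
      tr[[paste0("pre_", nm)]] <- pp[[nm]]
      tr[[paste0("post_", nm)]] <- qp[[nm]]
    }
    truth[[i]] <- tr

    for (r in raters) for (ph in c("pre", "post")) {
      op <- compute_panel(observed[[r]][[ph]])
      row <- data.frame(subject_id = paste(case_id, ph, sep = "_"),
                        rater = r)
      for (nm in PANEL_INDICES) row[[nm]] <- op[[nm]]
      ratings[[length(ratings) + 1L]] <- row
    }
  }

  if (rejected > n)
    warning(sprintf("%d infeasible draw(s) were rejected and resampled",
                    rejected))
  params <- list(n = n, anatomy = unclass(anatomy), anatomy_sd = anatomy_sd,
                 elevation_mean = elevation_mean, elevation_sd = elevation_sd,
                 shortening_mean = shortening_mean,
                 shortening_sd = shortening_sd,
                 noise = unclass(noise), raters = raters, seed = seed,
                 package_version = as.character(utils::packageVersion("patellaxis")))
  structure(list(cases = cases, ground_truth = do.call(rbind, truth),
                 ratings = do.call(rbind, ratings), params = params,
                 n_rejected = rejected),
            class = "knee_cohort")
}

#' @export
print.knee_cohort <- function(x, ...) {
  cat(sprintf("<knee_cohort> %d knees, %d rater(s), noise sigma %g mm, seed %d\n",
              length(x$cases), length(x$params$raters),
              x$params$noise$sigma_mm, x$params$seed))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Writes one landmark JSON per radiograph (noise-free and per-rater
#' observed copies), `ratings.csv`, `ground_truth.csv` and `manifest.json`
#' (the full resolved generation parameters). Output is deterministic for a
#' fixed seed: rerunning produces byte-identical files.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "knee_cohort"))
  lmdir <- file.path(dir, "landmarks")
  dir.create(lmdir, recursive = TRUE, showWarnings = FALSE)
  for (cs in cohort$cases) {
    for (ph in c("pre", "post"))
      write_landmarks(cs[[ph]],
                      file.path(lmdir, sprintf("%s_%s.json", cs$case_id, ph)))
    for (r in names(cs$observed)) for (ph in c("pre", "post"))
      write_landmarks(cs$observed[[r]][[ph]],
                      file.path(lmdir, sprintf("%s_%s_%s.json",
                                               cs$case_id, ph, r)))
  }
  utils::write.csv(cohort$ratings, file.path(dir, "ratings.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  jsonlite::write_json(cohort$params, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
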
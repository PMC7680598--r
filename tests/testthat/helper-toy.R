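# Worked-toy knee used throughout the tests: vertical shaft axis (x = 0),
# flat joint line (y = 0), fibular tip (14, 11), articular poles
# (-16, -12) / (-16, -37), patellar poles (-18, -10) / (-18, -42),
# tendon insertion (-18, 22), margin (-16, 4), shaft points (0, 70), (0, 110).
# Hand values: IS 1, mIS sqrt(1160)/25, CD 0.64, BP 0.48, AP sqrt(785)/25,
# jAP 0.8, JLH 11, PTS 0.

toy_anatomy <- function() {
  knee_anatomy(articular_length_b = 25, patella_length = 32,
               tendon_length = 32, plateau_slope_deg = 0,
               fibular_tip_offset = c(14, 11), margin_offset = 4,
               patella_anterior_offset = 16, patella_proximal_height = 12)
}

toy_pre <- function(case_id = "TOY") {
  generate_knee(toy_anatomy(), case_id = case_id)
}

# same knee after a pure 4 mm proximal joint-line elevation:
# AP unchanged, a2 = sqrt(320), jAP = sqrt(320)/25, JLH 15
toy_post <- function(case_id = "TOY") {
  apply_surgery(toy_pre(case_id), surgery_params(joint_line_shift_mm = 4))
}

# rigid motion + uniform scaling of every landmark
transform_landmarks <- function(lm, angle_deg = 0, tx = 0, ty = 0,
                                scale = 1) {
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  pts <- lapply(lm$points, function(p)
    as.numeric(scale * (R %*% p)) + c(tx, ty))
  knee_landmarks(case_id = lm$case_id, side = lm$side, phase = lm$phase,
                 points = pts, flexion_deg = lm$flexion_deg, mm_per_pixel = 1)
}

# random but geometrically valid landmark set: random anatomy, then a random
# rigid motion so no test ever relies on the generator's canonical frame
random_landmarks <- function(phase = c("pre", "post")) {
  phase <- match.arg(phase)
  anat <- knee_anatomy(
    articular_length_b = runif(1, 20, 36),
    patella_length = runif(1, 30, 50),
    tendon_length = runif(1, 30, 52),
    plateau_slope_deg = runif(1, 0, 18),
    fibular_tip_offset = c(runif(1, 8, 20), runif(1, 4, 18)),
    margin_offset = runif(1, 0.5, 6),
    patella_anterior_offset = runif(1, 10, 22),
    patella_proximal_height = runif(1, 12, 30))
  lm <- generate_knee(anat, case_id = "rnd")
  if (phase == "post")
    lm <- apply_surgery(lm, surgery_params(runif(1, -2, 8), runif(1, 0, 0.3)))
  transform_landmarks(lm, angle_deg = runif(1, -180, 180),
                      tx = runif(1, -50, 50), ty = runif(1, -50, 50))
}
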
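test_that("the generator reproduces the worked toy exactly", {
  lm <- toy_pre()
  expect_equal(unname(lm$points$articular_inferior_pole), c(-16, -12))
  expect_equal(unname(lm$points$articular_superior_pole), c(-16, -37))
  expect_equal(unname(lm$points$patella_inferior_pole), c(-18, -10))
  expect_equal(unname(lm$points$patella_superior_pole), c(-18, -42))
  expect_equal(unname(lm$points$tendon_insertion), c(-18, 22))
  expect_equal(unname(lm$points$tibia_anterosuperior_margin), c(-16, 4))
  expect_equal(unname(lm$points$fibular_head_tip), c(14, 11))
  expect_equal(unname(lm$points$shaft_mid_70), c(0, 70))
  expect_equal(unname(lm$points$shaft_mid_110), c(0, 110))
})

test_that("generated knees honour their parameters exactly", {
  set.seed(61)
  for (i in 1:25) {
    anat <- knee_anatomy(
      articular_length_b = runif(1, 20, 36),
      patella_length = runif(1, 30, 50),
      tendon_length = runif(1, 30, 52),
      plateau_slope_deg = runif(1, 0, 18),
      fibular_tip_offset = c(runif(1, 8, 20), runif(1, 4, 18)),
      margin_offset = runif(1, 0.5, 6),
      patella_anterior_offset = runif(1, 10, 22),
      patella_proximal_height = runif(1, 12, 30))
    lm <- generate_knee(anat)
    expect_equal(point_distance(lm$points$articular_superior_pole,
                                lm$points$articular_inferior_pole),
                 anat$articular_length_b, tolerance = 1e-9)
    expect_equal(point_distance(lm$points$patella_inferior_pole,
                                lm$points$tendon_insertion),
                 anat$tendon_length, tolerance = 1e-9)
    expect_equal(posterior_tibial_slope(lm), anat$plateau_slope_deg,
                 tolerance = 1e-9)
    jl <- joint_line(lm)
    expect_equal(point_line_distance(lm$points$shaft_mid_70, jl), 70,
                 tolerance = 1e-9)
    expect_equal(point_line_distance(lm$points$shaft_mid_110, jl), 110,
                 tolerance = 1e-9)
    expect_equal(point_line_distance(lm$points$articular_inferior_pole, jl),
                 anat$patella_proximal_height, tolerance = 1e-9)
    expect_equal(axis_indices(lm)$JLH, anat$fibular_tip_offset[2],
                 tolerance = 1e-9)
  }
})

test_that("infeasible anatomy is rejected with an explanatory error", {
  expect_error(generate_knee(knee_anatomy(patella_proximal_height = -45,
                                          patella_length = 40)),
               "infeasible")
  expect_error(knee_anatomy(articular_length_b = 0), "positive")
  expect_error(knee_anatomy(plateau_slope_deg = 25), "0, 20")
})

test_that("surgery moves exactly what it should", {
  pre <- toy_pre()
  # identity surgery changes nothing but the phase
  id <- apply_surgery(pre, surgery_params(0, 0))
  expect_equal(id$phase, "post")
  for (nm in names(pre$points))
    expect_equal(id$points[[nm]], pre$points[[nm]], tolerance = 1e-12)

  # 20% tendon shortening: IS drops by exactly 0.8, JLH untouched
  sh <- apply_surgery(pre, surgery_params(0, 0.2))
  expect_equal(insall_salvati(sh), 0.8 * insall_salvati(pre),
               tolerance = 1e-12)
  expect_equal(axis_indices(sh)$JLH, axis_indices(pre)$JLH,
               tolerance = 1e-12)
  expect_equal(sh$points$shaft_mid_70, pre$points$shaft_mid_70)
  expect_equal(sh$points$fibular_head_tip, pre$points$fibular_head_tip)
  expect_equal(sh$points$tendon_insertion, pre$points$tendon_insertion)

  # elevation reproduces the toy post-op values
  el <- apply_surgery(pre, surgery_params(4, 0))
  expect_equal(el$points$joint_line_a, pre$points$joint_line_a - c(0, 4))
  expect_equal(compute_panel(el)$JLH, 15, tolerance = 1e-12)

  expect_error(apply_surgery(el, surgery_params(1, 0)), "preoperative")
})

test_that("observation noise is deterministic, unbiased and independent", {
  lm <- toy_pre()
  nm0 <- noise_model(sigma_mm = 0, seed = 3)
  same <- observe_landmarks(lm, nm0, "obs1")
  for (p in names(lm$points))
    expect_equal(same$points[[p]], lm$points[[p]])

  nm <- noise_model(sigma_mm = 0.5, seed = 3)
  a <- observe_landmarks(lm, nm, "obs1")
  b <- observe_landmarks(lm, nm, "obs1")
  for (p in names(lm$points)) expect_equal(a$points[[p]], b$points[[p]])
  c_ <- observe_landmarks(lm, nm, "obs2")
  expect_false(isTRUE(all.equal(a$points$fibular_head_tip,
                                c_$points$fibular_head_tip)))

  # rater bias is systematic
  nb <- noise_model(sigma_mm = 0, rater_bias = list(obs2 = c(0.3, -0.2)),
                    seed = 3)
  biased <- observe_landmarks(lm, nb, "obs2")
  expect_equal(biased$points$fibular_head_tip,
               lm$points$fibular_head_tip + c(0.3, -0.2))

  # observation does not disturb the caller's RNG stream
  set.seed(99); x1 <- runif(1)
  set.seed(99); invisible(observe_landmarks(lm, nm, "obs1")); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("empirical noise SD matches sigma over many replicates", {
  lm <- toy_pre()
  sims <- vapply(1:10000, function(i) {
    nm <- noise_model(sigma_mm = 0.5, seed = i)
    observe_landmarks(lm, nm, "obs1")$points$fibular_head_tip
  }, numeric(2))
  devs <- sims - unname(lm$points$fibular_head_tip)
  expect_equal(sd(devs[1, ]), 0.5, tolerance = 0.02)
  expect_equal(sd(devs[2, ]), 0.5, tolerance = 0.02)
  expect_lt(abs(mean(devs)), 0.02)
})

test_that("noise-free cohorts are exactly consistent with their ground truth", {
  cohort <- generate_cohort(20, noise = noise_model(0, seed = 2), seed = 2,
                            raters = "obs1")
  for (i in seq_along(cohort$cases)) {
    cs <- cohort$cases[[i]]
    gt <- cohort$ground_truth[i, ]
    pre <- compute_panel(cs$observed$obs1$pre)
    post <- compute_panel(cs$observed$obs1$post)
    for (nm in c("IS", "mIS", "CD", "BP", "AP", "jAP", "JLH", "PTS")) {
      expect_equal(pre[[nm]], gt[[paste0("pre_", nm)]], tolerance = 1e-9)
      expect_equal(post[[nm]], gt[[paste0("post_", nm)]], tolerance = 1e-9)
    }
    # measured elevation equals the drawn shift exactly at zero noise
    expect_equal(gt$post_JLH - gt$pre_JLH, gt$joint_line_shift_mm,
                 tolerance = 1e-9)
  }
})

test_that("cohort generation is reproducible and writes byte-identical files", {
  c1 <- generate_cohort(4, seed = 31, raters = c("a", "b"))
  c2 <- generate_cohort(4, seed = 31, raters = c("a", "b"))
  expect_identical(c1$ground_truth, c2$ground_truth)
  expect_identical(c1$ratings, c2$ratings)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(c1, d1); write_cohort(c2, d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1)
    expect_identical(readBin(file.path(d1, f), "raw",
                             file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw",
                             file.size(file.path(d2, f))),
                     info = f)
})

test_that("a degenerate single-case cohort reproduces the toy pair", {
  zero_sd <- anatomy_variation(0, 0, 0, 0, 0, 0, 0, 0, 0)
  cohort <- generate_cohort(1, anatomy = toy_anatomy(), anatomy_sd = zero_sd,
                            elevation_mean = 4, elevation_sd = 0,
                            noise = noise_model(0, seed = 1),
                            raters = "obs1", seed = 1)
  gt <- cohort$ground_truth
  expect_equal(gt$pre_JLH, 11, tolerance = 1e-9)
  expect_equal(gt$post_JLH, 15, tolerance = 1e-9)
  expect_equal(gt$post_jAP, sqrt(320) / 25, tolerance = 1e-9)
  expect_equal(gt$pre_AP, gt$post_AP, tolerance = 1e-9)
})
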
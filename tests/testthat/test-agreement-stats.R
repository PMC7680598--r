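test_that("perfect agreement gives ICC 1 and offsets separate the ICC forms", {
  m <- cbind(c(1.1, 2.3, 0.7, 1.9, 1.4), c(1.1, 2.3, 0.7, 1.9, 1.4))
  expect_equal(icc(m, "ICC(2,1)")$icc, 1, tolerance = 1e-12)
  expect_equal(icc(m, "ICC(3,1)")$icc, 1, tolerance = 1e-12)

  # a constant rater offset leaves consistency perfect but not agreement
  m2 <- cbind(m[, 1], m[, 1] + 0.5)
  expect_equal(icc(m2, "ICC(3,1)")$icc, 1, tolerance = 1e-12)
  expect_lt(icc(m2, "ICC(2,1)")$icc, 1)
})

test_that("ICC matches the aov()-based mean-squares oracle on random matrices", {
  set.seed(23)
  for (i in 1:100) {
    n <- sample(4:30, 1); k <- sample(2:5, 1)
    m <- matrix(rnorm(n * k, mean = rnorm(n, sd = 0.5), sd = 0.2), n, k) +
      outer(rep(1, n), rnorm(k, sd = 0.1))
    expect_equal(icc(m, "ICC(2,1)")$icc, oracle_icc_21(m), tolerance = 1e-9)
    expect_equal(icc(m, "ICC(3,1)")$icc, oracle_icc_31(m), tolerance = 1e-9)
    expect_equal(icc(m, "ICC(1,1)")$icc, oracle_icc_11(m), tolerance = 1e-9)
  }
})

test_that("ICC is invariant to common shifts and positive rescaling", {
  set.seed(31)
  m <- matrix(rnorm(40, 10, 2), 20, 2)
  r0 <- icc(m)$icc
  expect_equal(icc(m + 7)$icc, r0, tolerance = 1e-9)
  expect_equal(icc(m * 3.5)$icc, r0, tolerance = 1e-9)
})

test_that("simulated variance components recover the analytic ICC", {
  set.seed(97)
  n <- 500; k <- 2
  subj <- rnorm(n, 0, 0.15)
  m <- outer(subj, rep(1, k)) + matrix(rnorm(n * k, 0, 0.05), n, k)
  r <- icc(m, "ICC(2,1)")
  expect_equal(r$icc, 0.0225 / 0.0250, tolerance = 0.02)
  expect_lte(r$ci95[["low"]], r$icc)
  expect_gte(r$ci95[["high"]], r$icc)
  expect_lt(r$p_value, 1e-6)
})

test_that("degenerate ratings matrices are rejected", {
  expect_error(icc(matrix(1, 5, 2)), "zero total variance")
  expect_error(icc(matrix(rnorm(4), 2, 2)), "3 subjects")
  expect_error(icc(matrix(rnorm(5), 5, 1)), "2 raters")
  expect_error(icc(matrix(c(1, NA, 2, 3, 4, 5), 3, 2)), "missing")
})

test_that("paired t test matches hand values and the closed form", {
  r <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$mean_diff, 0)
  expect_equal(r$t, 0)
  expect_equal(r$p_value, 1)
  expect_true(r$degenerate)

  r2 <- paired_t(c(0, 0, 0), c(-1, 0, 1))
  expect_equal(r2$mean_diff, 0)
  expect_equal(r2$t, 0)

  r3 <- paired_t(c(1, 2), c(2, 3))  # constant nonzero difference
  expect_equal(r3$t, Inf)
  expect_equal(r3$p_value, 0)
  expect_true(r3$degenerate)

  set.seed(13)
  for (i in 1:100) {
    n <- sample(3:40, 1)
    pre <- rnorm(n); post <- rnorm(n, 0.3)
    r <- paired_t(pre, post)
    d <- post - pre
    expect_equal(r$t, mean(d) / (sd(d) / sqrt(n)), tolerance = 1e-9)
    expect_equal(r$p_value, 2 * pt(-abs(r$t), n - 1), tolerance = 1e-9)
  }
})

test_that("Bland-Altman matches hand values and its translation property", {
  r <- bland_altman(c(0, 0, 0), c(1, 0, -1))  # differences {-1, 0, 1}
  expect_equal(r$bias, 0)
  expect_equal(r$sd_diff, 1)
  expect_equal(r$loa_low, -1.96)
  expect_equal(r$loa_high, 1.96)

  same <- bland_altman(c(1.2, 3.4, 5.6), c(1.2, 3.4, 5.6))
  expect_equal(same$bias, 0)
  expect_equal(c(same$loa_low, same$loa_high), c(0, 0))

  set.seed(5)
  m1 <- rnorm(30); m2 <- rnorm(30)
  a <- bland_altman(m1, m2)
  b <- bland_altman(m1, m2 + 2)   # adding c to m2 shifts bias by -c
  expect_equal(b$bias, a$bias - 2, tolerance = 1e-12)
  expect_equal(b$sd_diff, a$sd_diff, tolerance = 1e-12)
  rev <- bland_altman(m2, m1)     # argument reversal negates everything
  expect_equal(rev$bias, -a$bias, tolerance = 1e-12)
  expect_equal(rev$loa_low, -a$loa_high, tolerance = 1e-12)
})

test_that("the Pearson matrix is symmetric with unit diagonal and flags constants", {
  set.seed(77)
  cohort <- generate_cohort(12, noise = noise_model(0, seed = 1), seed = 4,
                            raters = "obs1")
  panels <- lapply(cohort$cases, function(cs) compute_panel(cs$pre))
  r <- pearson_matrix(panels, phase = "pre")
  expect_true(isSymmetric(unname(r)))
  expect_true(all(diag(r)[!is.na(diag(r))] == 1))
  expect_equal(sort(colnames(r)),
               sort(c("PTS", "AP", "jAP", "IS", "mIS", "CD", "BP", "JLH")))

  # exact linear dependence gives r = 1; negation gives -1
  df <- panel_table(panels)
  df$AP <- 2 * df$jAP + 3
  df$IS <- -df$jAP
  r2 <- pearson_matrix(df)
  expect_equal(unname(r2["AP", "jAP"]), 1, tolerance = 1e-12)
  expect_equal(unname(r2["IS", "jAP"]), -1, tolerance = 1e-12)

  df$CD <- 0.8  # constant column: undefined correlation, flagged
  r3 <- pearson_matrix(df)
  expect_true(all(is.na(r3["CD", ])))
  expect_true("CD" %in% attr(r3, "constant"))
})

test_that("cohort summary reproduces clone and single-pair edge cases", {
  pre <- compute_panel(toy_pre())
  post <- compute_panel(toy_post())
  pair <- paired_deltas(pre, post)

  s1 <- cohort_summary(list(pair))
  expect_true(all(is.na(s1$p_value)))
  expect_equal(s1$pre_mean[s1$index == "JLH"], 11)
  expect_equal(s1$post_mean[s1$index == "JLH (post-pre)"], 4)

  s3 <- cohort_summary(list(pair, pair, pair))
  expect_true(all(s3$pre_sd[s3$index %in% c("IS", "JLH")] == 0))
  expect_equal(s3$post_mean[s3$index == "AP"], post$AP)
})

test_that("reliability_table computes one ICC row per index", {
  set.seed(8)
  subj <- sprintf("s%02d", 1:20)
  truth <- rnorm(20, 1.3, 0.15)
  ratings <- do.call(rbind, lapply(c("r1", "r2"), function(r)
    data.frame(subject_id = subj, rater = r,
               AP = truth + rnorm(20, 0, 0.05),
               jAP = truth - 0.3 + rnorm(20, 0, 0.05))))
  tab <- reliability_table(ratings)
  expect_equal(tab$index, c("AP", "jAP"))
  expect_true(all(tab$icc > 0.5 & tab$icc <= 1))
  expect_true(all(tab$ci_low <= tab$icc & tab$icc <= tab$ci_high))
  dup <- ratings
  dup$AP[dup$rater == "r2"] <- dup$AP[dup$rater == "r1"]
  expect_equal(reliability_table(dup, indices = "AP")$icc, 1,
               tolerance = 1e-12)
})
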
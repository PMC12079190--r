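# Activation mapping: HRF kernel, design matrix, voxelwise GLM, FDR.

test_that("gamma HRF has the analytic peak, onset delay and unit maximum", {
  h <- gamma_hrf(dt = 0.01)
  t <- seq(0, 15, by = 0.01)
  expect_equal(t[which.max(h)], 2.9, tolerance = 0.005 + 1e-9)
  expect_true(all(h[t < 1.5] == 0))
  expect_equal(max(h), 1)
  h2 <- gamma_hrf(dt = 0.5)
  expect_lte(abs(seq(0, 15, 0.5)[which.max(h2)] - 2.9), 0.25)
  expect_error(gamma_hrf(dt = 0), "positive")
  expect_error(gamma_hrf(dt = 0.1, duration = 1), "delay")
})

test_that("design matrix convolves the boxcar and rejects empty designs", {
  p <- default_protocol()
  kern <- gamma_hrf(dt = 0.5)
  des <- build_design_matrix(p, kern, 190, 2)
  expect_equal(colnames(des), c("task", "intercept"))
  expect_equal(max(des[, 1]), 1)
  times <- attr(des, "times")
  expect_lt(max(abs(des[times < 20 + 1.5, 1])), 1e-10)  # support starts at onset+delta
  expect_true(any(des[times > 23, 1] > 0.5))

  null_p <- stimulus_protocol(5, numeric(0), numeric(0), 20)
  expect_error(build_design_matrix(null_p, kern, 40, 2), "at least one")

  imp <- structure(c(1, rep(0, 10)), dt = 0.5)
  des_imp <- build_design_matrix(p, imp, 190, 2)
  box <- as.numeric(times >= 20 & times < 25 | times >= 45 & times < 50 |
                      times >= 70 & times < 75)
  expect_equal(as.numeric(des_imp[, 1]), box)
})

test_that("the GLM recovers exact linear relationships", {
  des <- build_design_matrix(default_protocol(), gamma_hrf(dt = 0.5), 190, 2)
  y1 <- matrix(des[, 1], ncol = 1)
  a1 <- fit_glm(y1, des)
  expect_equal(a1$beta, 1)
  expect_lt(a1$p_value, 1e-12)

  y2 <- matrix(2 * des[, 1] + 3, ncol = 1)
  a2 <- fit_glm(y2, des)
  expect_equal(a2$beta, 2, tolerance = 1e-8)
  expect_equal(a2$intercept, 3, tolerance = 1e-8)
  expect_equal(a2$dof, 188)
})

test_that("the GLM agrees with normal equations and lm()", {
  set.seed(41)
  des <- build_design_matrix(default_protocol(), gamma_hrf(dt = 0.5), 60, 2)
  for (i in 1:20) {
    y <- rnorm(60) + rnorm(1) * des[, 1]
    a <- fit_glm(matrix(y, ncol = 1), des)
    o <- glm_oracle(y, unclass(des))
    expect_equal(a$beta, o$beta, tolerance = 1e-8)
    expect_equal(a$t_score, o$t, tolerance = 1e-8)
    expect_equal(a$p_value, o$p, tolerance = 1e-8)
    lmf <- summary(lm(y ~ 0 + des[, 1] + des[, 2]))$coefficients
    expect_equal(a$t_score, lmf[1, 3], tolerance = 1e-8)
  }
})

test_that("null voxels give calibrated type-I error", {
  set.seed(42)
  des <- build_design_matrix(default_protocol(), gamma_hrf(dt = 0.5), 190, 2)
  y <- matrix(rnorm(190 * 10000), 190, 10000)
  a <- fit_glm(y, des)
  expect_lt(abs(mean(a$p_value < 0.05) - 0.05), 0.01)
})

test_that("smoothing-corrected GLM stays calibrated on smoothed null data", {
  set.seed(43)
  des <- build_design_matrix(default_protocol(), gamma_hrf(dt = 0.5), 190, 2)
  s <- fusact:::smoothing_matrix(190, 5L)
  y <- s %*% matrix(rnorm(190 * 4000), 190, 4000)
  a <- fit_glm(y, des, temporal_smoothing = 5L)
  expect_lt(abs(mean(a$p_value < 0.05) - 0.05), 0.015)
  expect_lt(a$dof, 180)  # effective dof shrinks under smoothing
  # without the correction the t-scores are visibly inflated
  a0 <- fit_glm(y, des)
  expect_gt(stats::sd(a0$t_score), 2)
  expect_equal(stats::sd(a$t_score), 1, tolerance = 0.1)
})

test_that("invalid voxels propagate NaN and rank deficiency errors raise", {
  des <- build_design_matrix(default_protocol(), gamma_hrf(dt = 0.5), 60, 2)
  y <- matrix(rnorm(120), 60, 2)
  y[3, 2] <- NaN
  a <- fit_glm(y, des)
  expect_true(is.finite(a$p_value[1]))
  expect_true(is.nan(a$p_value[2]))
  bad <- cbind(des[, 1], des[, 1])
  expect_error(fit_glm(y, structure(bad, class = class(des))), "rank")
})

test_that("BH adjustment matches the hand example and brute-force oracle", {
  f <- fdr_correct(c(0.0001, 0.5, 0.9), q = 0.001)
  expect_equal(f$q_value, c(0.0003, 0.75, 0.9))
  expect_equal(sum(f$mask), 1L)

  expect_false(any(fdr_correct(rep(1, 5), 0.001)$mask))

  p_nan <- c(0.001, NaN, 0.2)
  fn <- fdr_correct(p_nan, 0.01)
  expect_true(is.nan(fn$q_value[2]))

  set.seed(44)
  for (i in 1:50) {
    p <- runif(sample(3:20, 1))
    expect_equal(fdr_correct(p, 0.05)$q_value, bh_oracle(p), tolerance = 1e-12)
  }
  expect_error(fdr_correct(c(-0.1, 0.5)), "\\[0, 1\\]")
})

test_that("BH matches p.adjust cross-check", {
  set.seed(45)
  p <- runif(500)^2
  expect_equal(fdr_correct(p, 0.05)$q_value, p.adjust(p, "BH"))
})

test_that("activation pipeline recovers the injected activation", {
  run <- full_run()
  act <- run$act
  am <- run$scene$activation_mask
  expect_gte(mean(act$mask[am]), 0.8)          # sensitivity on active voxels
  far <- scene_background_mask(run$scene, margin = 5L)
  expect_lte(mean(act$mask[far]), 0.001)       # FDR control far from vessels
  expect_equal(act$threshold$correction, "BH")
  expect_true(act$threshold$n_uncorrected >= act$threshold$n_corrected)
})

test_that("null phantoms give uniform voxel p-values on vessels", {
  acq <- acq_params()
  scene <- make_phantom(c(32, 32), 3, effect_size = 0, seed = 6, acq = acq)
  prot <- stimulus_protocol(10, c(10, 25), c(5, 5), 40)
  seq <- simulate_compound_frames(scene, prot, acq, seed = 7,
                                  motion = motion_model("none"))
  pd <- doppler_movie(seq)
  ns <- preprocess_series(pd, prot, motion_correct = FALSE, sigma = 0,
                          window = 1)
  des <- build_design_matrix(prot, gamma_hrf(dt = 0.5), dim(ns$values)[1], 2)
  act <- fit_glm(ns, des)
  pv <- act$p_value[scene_vessel_mask(scene)]
  expect_gte(length(pv), 200)
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
})

test_that("stronger effects never lose true discoveries (paired seeds)", {
  acq <- acq_params()
  prot <- stimulus_protocol(10, c(10, 25), c(5, 5), 40)
  n_disc <- sapply(c(0.08, 0.16), function(es) {
    scene <- make_phantom(c(24, 24), 2, effect_size = es, seed = 8, acq = acq)
    seq <- simulate_compound_frames(scene, prot, acq, seed = 9)
    act <- activation_pipeline(doppler_movie(seq), prot)
    sum(act$mask[scene$activation_mask])
  })
  expect_gte(n_disc[2], n_disc[1])
})
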
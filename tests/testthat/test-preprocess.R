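# Preprocessing: motion correction, spatial/temporal smoothing, voxel
# normalization.

smooth_test_image <- function(n = 48, seed = 31) {
  set.seed(seed)
  k <- dnorm(-6:6, sd = 2); k <- k / sum(k)
  fusact:::conv_matrix_reflect(n, k) %*% matrix(rnorm(n * n), n, n) %*%
    t(fusact:::conv_matrix_reflect(n, k)) + 2
}

test_that("motion correction recovers injected translations", {
  base <- smooth_test_image()
  imgs <- array(0, c(6, 48, 48))
  for (t in 1:6) imgs[t, , ] <- base
  imgs[5, , ] <- fusact:::shift_image(base, 2, 0)
  imgs[6, , ] <- fusact:::shift_image(base, -1, 1.5)
  pd <- as_pd_series(imgs)
  out <- correct_motion(pd)
  expect_equal(out$motion_log$dz[1], 0)  # reference frame
  expect_lt(max(abs(out$motion_log$dz[2:4])), 0.1)  # nothing to correct
  expect_equal(out$motion_log$dz[5], 2, tolerance = 0.25)
  expect_equal(out$motion_log$dz[6], -1, tolerance = 0.25)
  expect_equal(out$motion_log$dx[6], 1.5, tolerance = 0.25)
})

test_that("correction reduces residual displacement by >= 75%", {
  base <- smooth_test_image(seed = 32)
  n <- 12
  set.seed(33)
  dz <- runif(n, -2, 2); dx <- runif(n, -2, 2)
  dz[1] <- 0; dx[1] <- 0
  imgs <- array(0, c(n, 48, 48))
  for (t in 1:n) imgs[t, , ] <- fusact:::shift_image(base, dz[t], dx[t])
  corrected <- correct_motion(as_pd_series(imgs))
  resid <- correct_motion(corrected)$motion_log  # re-estimate what is left
  before <- mean(sqrt(dz^2 + dx^2))
  after <- mean(sqrt(resid$dz^2 + resid$dx^2))
  expect_lt(after, 0.25 * before)
})

test_that("flat frames yield a warning and identity transform", {
  imgs <- array(0, c(3, 16, 16))
  imgs[1, , ] <- matrix(rnorm(256), 16, 16)
  expect_warning(out <- correct_motion(as_pd_series(imgs)), "registration")
  expect_true(all(is.na(out$motion_log$dz[2:3])))
})

test_that("spatial smoothing preserves DC and reproduces the Gaussian peak", {
  const <- as_pd_series(array(3.7, c(2, 20, 20)))
  expect_equal(spatial_smooth(const, 1)$images, const$images)

  imp <- array(0, c(1, 21, 21)); imp[1, 11, 11] <- 1
  sm <- spatial_smooth(as_pd_series(imp), 1)
  expect_equal(sm$images[1, 11, 11], 1 / (2 * pi), tolerance = 0.02)

  noisy <- as_pd_series(array(rnorm(2 * 16 * 16), c(2, 16, 16)))
  expect_identical(spatial_smooth(noisy, 0)$images, noisy$images)
  expect_error(spatial_smooth(noisy, -1), ">= 0")
})

test_that("voxel normalization computes percent change and demeaning", {
  vals <- array(100, c(10, 4, 4))
  vals[6:10, 2, 2] <- 110
  pd <- as_pd_series(vals)  # timestamps 0.25..4.75 s
  ns <- normalize_voxels(pd, reference_window = c(0, 2.5))
  expect_equal(ns$values[, 1, 1], rep(0, 10))
  expect_equal(ns$values[6:10, 2, 2], rep(10, 10 - 5))
  expect_lt(abs(mean(ns$values[ns$reference_blocks, 2, 2])), 1e-6)

  dm <- normalize_voxels(as_pd_series(array(rep(1:3, 16), c(3, 4, 4))),
                         mode = "demean")
  expect_equal(dm$values[, 1, 1], c(-1, 0, 1))
  dm2 <- normalize_voxels(dm, mode = "demean")
  expect_equal(dm2$values, dm$values)  # idempotent

  vals0 <- array(1, c(4, 4, 4)); vals0[, 3, 3] <- 0
  nz <- normalize_voxels(as_pd_series(vals0))
  expect_true(nz$invalid[3, 3])
  expect_true(all(is.nan(nz$values[, 3, 3])))
  expect_error(normalize_voxels(pd, reference_window = c(90, 95)), "no blocks")
})

test_that("temporal smoothing is a centered shrinking-window average", {
  const <- as_pd_series(array(2.2, c(9, 3, 3)))
  expect_equal(temporal_smooth(const, 5)$images, const$images)

  imp <- array(0, c(11, 2, 2)); imp[6, 1, 1] <- 5
  sm <- temporal_smooth(as_pd_series(imp), 5)
  expect_equal(sm$images[, 1, 1], c(0, 0, 0, 1, 1, 1, 1, 1, 0, 0, 0))

  x <- as_pd_series(array(rnorm(36), c(4, 3, 3)))
  expect_identical(temporal_smooth(x, 1)$images, x$images)
  expect_error(temporal_smooth(x, 4), "odd")
})

test_that("the preprocessing chain runs in the documented order", {
  run <- full_run()
  steps <- attr(run$series, "steps")
  expect_match(steps[1], "motion")
  expect_match(steps[2], "spatial_smooth")
  expect_match(steps[3], "normalize")
  expect_match(steps[4], "temporal_smooth")
  expect_s3_class(run$series, "fus_norm_series")
  expect_equal(run$series$normalization_mode, "percent_change")
})
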
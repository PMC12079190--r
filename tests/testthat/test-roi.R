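# ROI statistics: time-course extraction, z-scores, stimulus-response
# tests, ROI selection.

test_that("ROI time courses are unweighted spatial means", {
  vals <- array(0, c(3, 8, 8))
  vals[, 2, 3] <- c(5, 6, 7)
  pd <- as_pd_series(vals)
  one <- roi_spec(z0 = 1 * 2e-4, x0 = 2 * 2e-4, height = 2e-4, width = 2e-4)
  expect_equal(one$rows, c(2, 2)); expect_equal(one$cols, c(3, 3))
  expect_equal(as.numeric(extract_roi_timeseries(pd, one)), c(5, 6, 7))

  u <- as_pd_series(array(4.2, c(2, 8, 8)))
  big <- roi_spec(0, 0, 8 * 2e-4, 8 * 2e-4)
  expect_equal(as.numeric(extract_roi_timeseries(u, big)), c(4.2, 4.2))

  q <- array(0, c(1, 8, 8)); q[1, 1:2, 1:2] <- c(1, 3, 2, 4)
  expect_equal(as.numeric(
    extract_roi_timeseries(as_pd_series(q), roi_spec(0, 0, 4e-4, 4e-4))), 2.5)

  expect_error(extract_roi_timeseries(u, roi_spec(7 * 2e-4, 0)), "exceeds")
})

test_that("invalid voxels are excluded from the ROI mean with a count", {
  vals <- array(1, c(4, 8, 8))
  vals[, 1, 2] <- NaN
  tc <- extract_roi_timeseries(as_pd_series(vals), roi_spec(0, 0, 4e-4, 4e-4))
  expect_equal(as.numeric(tc), rep(1, 4))
  expect_equal(attr(tc, "n_excluded"), 1L)
  all_bad <- array(NaN, c(2, 8, 8))
  expect_error(
    extract_roi_timeseries(as_pd_series(all_bad), roi_spec(0, 0, 4e-4, 4e-4)),
    "empty")
})

test_that("z-scores are measured against the baseline window", {
  tc <- c(0, 2, 3)
  z <- zscore_timecourse(tc, 1:2)
  expect_equal(z[3], sqrt(2))
  expect_equal(mean(z[1:2]), 0)
  expect_equal(stats::sd(z[1:2]), 1)
  flat <- c(1, 1, 5)
  expect_error(zscore_timecourse(flat, 1:2), "variance")
  long <- rnorm(50)
  zz <- zscore_timecourse(long, 1:20)
  expect_equal(mean(zz[1:20]), 0, tolerance = 1e-12)
  expect_equal(stats::sd(zz[1:20]), 1, tolerance = 1e-12)
})

test_that("zero-noise step responses are recovered exactly", {
  prot <- default_protocol()
  # block centers at 2 Hz; step of +5 exactly on the lag-shifted windows
  w <- fusact:::protocol_windows(190, prot, 2, lag = 2.9)
  tc <- rep(10, 190)
  tc[w$stim] <- 15
  st <- stim_response_stats(tc, prot, 2)
  expect_equal(st$mean_diff_percent, 5)
  expect_equal(st$per_stimulus_means, rep(15, 3))
  expect_identical(st$p_value, 0)  # noise-free separation
  expect_equal(st$n_stim, length(w$stim))
})

test_that("an 11.95% injected step is recovered within its CI at default noise", {
  prot <- default_protocol()
  w <- fusact:::protocol_windows(190, prot, 2, lag = 2.9)
  set.seed(51)
  est <- replicate(50, {
    tc <- rnorm(190, sd = 1)
    tc[w$stim] <- tc[w$stim] + 11.95
    stim_response_stats(tc, prot, 2)$mean_diff_percent
  })
  expect_equal(mean(est), 11.95, tolerance = 0.15)
  tcq <- rnorm(190); tcq[w$stim] <- tcq[w$stim] + 11.95
  expect_lt(stim_response_stats(tcq, prot, 2)$p_value, 1e-3)
})

test_that("the stimulus-response t-test is calibrated under the null", {
  prot <- default_protocol()
  set.seed(52)
  pvals <- replicate(500, stim_response_stats(rnorm(190), prot, 2)$p_value)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.02)
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("rest modes and test variants are selectable", {
  prot <- default_protocol()
  set.seed(53)
  tc <- rnorm(190)
  a <- stim_response_stats(tc, prot, 2, rest_mode = "baseline")
  b <- stim_response_stats(tc, prot, 2, rest_mode = "pooled")
  expect_lt(a$n_pre, b$n_pre)
  s <- stim_response_stats(tc, prot, 2, var_equal = TRUE)
  expect_equal(s$test, "student")
  expect_equal(s$df, s$n_stim + s$n_pre - 2)
  short <- stimulus_protocol(1, 1, 0.5, 2)
  expect_error(stim_response_stats(rnorm(4), short, 2), ">= 2 samples")
})

test_that("percent-change ROI statistics are invariant to PD rescaling", {
  run <- full_run()
  pd2 <- run$pd
  pd2$images <- pd2$images * 3.7
  roi <- roi_spec(10 * 2e-4, 10 * 2e-4)
  get_stats <- function(pd) {
    ns <- preprocess_series(pd, run$protocol, motion_correct = FALSE)
    st <- stim_response_stats(extract_roi_timeseries(ns, roi),
                              run$protocol, pd$block_rate)
    c(st$mean_diff_percent, st$z_course)
  }
  expect_equal(get_stats(run$pd), get_stats(pd2), tolerance = 1e-10)
})

test_that("ROI selection matches a brute-force scan", {
  set.seed(54)
  for (i in 1:5) {
    tmap <- matrix(rnorm(32 * 32), 32, 32)
    pdm <- matrix(runif(32 * 32), 32, 32)
    act <- list(t_score = tmap)
    sel <- select_rois(act, pdm, roi_size_m = 1.6e-3)  # 8 x 8 px
    o <- select_rois_oracle(tmap, pdm, 8, 8)
    expect_equal(c(sel$reactive[[1]]$rows[1], sel$reactive[[1]]$cols[1]),
                 o$reactive)
    expect_equal(c(sel$nonreactive[[1]]$rows[1], sel$nonreactive[[1]]$cols[1]),
                 o$nonreactive)
  }
})

test_that("ROI selection handles hot blocks, fallbacks and thresholds", {
  tmap <- matrix(0, 32, 32)
  tmap[12:13, 20:21] <- 10
  act <- list(t_score = tmap)
  sel <- select_rois(act, matrix(1 + 0 * tmap, 32, 32), roi_size_m = 4e-4,
                     vascular_quantile = 0)
  expect_equal(sel$reactive[[1]]$rows, c(12, 13))
  expect_equal(sel$reactive[[1]]$cols, c(20, 21))

  expect_warning(
    selz <- select_rois(list(t_score = matrix(0, 32, 32)),
                        matrix(runif(1024), 32, 32)),
    "vascular-intensity")
  expect_length(selz$reactive, 1L)

  expect_error(select_rois(act, matrix(1, 32, 32), roi_size_m = 1),
               "exceeds the grid")
})

test_that("selected reactive/nonreactive ROIs do not overlap for n_each > 1", {
  set.seed(55)
  tmap <- matrix(rnorm(1024), 32, 32)
  sel <- select_rois(list(t_score = tmap), matrix(1, 32, 32),
                     roi_size_m = 1.6e-3, n_each = 3, vascular_quantile = 0)
  boxes <- t(sapply(sel$reactive, function(r) c(r$rows[1], r$cols[1])))
  for (i in 1:2) for (j in (i + 1):3) {
    expect_true(abs(boxes[i, 1] - boxes[j, 1]) >= 8 ||
                  abs(boxes[i, 2] - boxes[j, 2]) >= 8)
  }
})

test_that("null ROI mean differences center at zero across seeds", {
  prot <- default_protocol()
  set.seed(56)
  diffs <- replicate(200, stim_response_stats(rnorm(190), prot,
                                              2)$mean_diff_percent)
  expect_lt(abs(mean(diffs)), 0.05)
})
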
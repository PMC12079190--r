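# ROI-level analysis: time courses, baseline z-scores, stimulation-response
# statistics, and data-driven reactive / nonreactive ROI selection.

#' Rectangular region of interest
#'
#' A rectangle in physical units (meters), converted to half-open 0-based
#' pixel bounds through the pixel spacings: pixel rows
#' `floor(z0 / spacing_z) .. floor(z0 / spacing_z) + round(height /
#' spacing_z) - 1`, analogously for columns. The conventional ROI size is
#' about 2 mm x 2 mm.
#'
#' @param z0,x0 Top-left corner in meters (depth, lateral).
#' @param height,width Extent in meters (default 2 mm).
#' @param spacing_z,spacing_x Pixel spacings in meters/pixel.
#' @param label `"reactive"`, `"nonreactive"` or `"custom"`.
#' @return Object of class `fus_roi_spec` with 1-based inclusive pixel
#'   bounds `$rows`, `$cols`.
#' @export
roi_spec <- function(z0, x0, height = 2e-3, width = 2e-3,
                     spacing_z = 2e-4, spacing_x = 2e-4,
                     label = c("custom", "reactive", "nonreactive")) {
  label <- match.arg(label)
  if (height <= 0 || width <= 0) stopf("ROI must have positive area")
  r0 <- floor(z0 / spacing_z) + 1L
  c0 <- floor(x0 / spacing_x) + 1L
  nr <- max(1L, round(height / spacing_z))
  nc <- max(1L, round(width / spacing_x))
  structure(list(
    z0 = z0, x0 = x0, height = height, width = width,
    spacing_z = spacing_z, spacing_x = spacing_x,
    rows = unname(c(r0, r0 + nr - 1L)), cols = unname(c(c0, c0 + nc - 1L)),
    label = label
  ), class = "fus_roi_spec")
}

# Pixel-bounds constructor (used by select_rois).
roi_from_pixels <- function(r0, c0, nr, nc, spacing_z, spacing_x, label) {
  roi_spec(z0 = (r0 - 1L) * spacing_z, x0 = (c0 - 1L) * spacing_x,
           height = nr * spacing_z, width = nc * spacing_x,
           spacing_z = spacing_z, spacing_x = spacing_x, label = label)
}

#' @export
print.fus_roi_spec <- function(x, ...) {
  cat(sprintf("ROI [%s]: rows %d-%d, cols %d-%d (%.2g x %.2g mm)\n",
              x$label, x$rows[1], x$rows[2], x$cols[1], x$cols[2],
              x$height * 1e3, x$width * 1e3))
  invisible(x)
}

#' ROI time course
#'
#' Unweighted spatial mean over the ROI pixels for every frame. Voxels
#' flagged invalid by normalization (`NaN` series) are excluded; their
#' count is recorded in the `"n_excluded"` attribute.
#'
#' @param series `fus_pd_series` or `fus_norm_series`.
#' @param roi [roi_spec()], fully inside the grid.
#' @return Numeric time course (one value per block frame).
#' @export
extract_roi_timeseries <- function(series, roi) {
  vals <- series_values(series)
  d <- dim(vals)
  if (roi$rows[1] < 1L || roi$cols[1] < 1L ||
      roi$rows[2] > d[2] || roi$cols[2] > d[3])
    stopf("ROI (rows %d-%d, cols %d-%d) exceeds the %d x %d grid",
          roi$rows[1], roi$rows[2], roi$cols[1], roi$cols[2], d[2], d[3])
  sub <- vals[, roi$rows[1]:roi$rows[2], roi$cols[1]:roi$cols[2],
              drop = FALSE]
  dim(sub) <- c(d[1], length(sub) / d[1])
  bad <- colSums(!is.finite(sub)) > 0L
  if (all(bad)) stopf("ROI is empty after excluding invalid voxels")
  tc <- rowMeans(sub[, !bad, drop = FALSE])
  attr(tc, "n_excluded") <- sum(bad)
  tc
}

#' Baseline z-score time course
#'
#' Standard scores against the baseline window:
#' `z(t) = (tc(t) - mean_base) / sd_base` with the sample (n-1) standard
#' deviation, yielding a time-resolved activation response.
#'
#' @param tc Numeric time course.
#' @param baseline_idx Integer indices of the baseline samples (>= 2).
#' @return Numeric z-score time course.
#' @export
zscore_timecourse <- function(tc, baseline_idx) {
  if (length(baseline_idx) < 2L) stopf("baseline window needs >= 2 samples")
  mu <- mean(tc[baseline_idx])
  s <- stats::sd(tc[baseline_idx])
  if (!is.finite(s) || s <= 0)
    stopf("baseline has zero variance; check the series noise floor")
  (tc - mu) / s
}

# Block indices of the (lag-shifted) stimulation windows and of the rest
# windows under the chosen mode. Transition periods (from each onset to the
# lagged window start, and one lag after the window end) belong to neither.
protocol_windows <- function(tc_len, protocol, block_rate, lag,
                             rest_mode = c("pooled", "baseline")) {
  rest_mode <- match.arg(rest_mode)
  times <- (seq_len(tc_len) - 0.5) / block_rate
  stim <- rep(FALSE, tc_len)
  excl <- rep(FALSE, tc_len)
  for (i in seq_along(protocol$onsets)) {
    on <- protocol$onsets[i]; du <- protocol$durations[i]
    stim <- stim | (times >= on + lag & times < on + du + lag)
    excl <- excl | (times >= on & times < on + du + 2 * lag)
  }
  rest <- if (rest_mode == "baseline") {
    times < protocol$baseline_duration
  } else {
    !excl & !stim
  }
  list(stim = which(stim), rest = which(rest & !stim), times = times)
}

#' Stimulation-response statistics for an ROI time course
#'
#' Compares the response during the (hemodynamically lagged) stimulation
#' windows with rest. Stimulation samples are blocks whose centers fall in
#' `[onset + lag, onset + duration + lag)`; the default lag is the HRF peak
#' time (2.9 s for the default parameters). Rest samples are either all
#' pooled rest blocks outside the stimulus/transition windows (default) or
#' the pre-stimulus baseline only. Reports the mean stimulation-minus-rest
#' difference, a two-sided Welch t-test (Student's pooled test optional),
#' per-stimulus means, and the baseline z-score course.
#'
#' @param tc Numeric ROI time course (percent change per block under the
#'   default normalization).
#' @param protocol [stimulus_protocol()].
#' @param block_rate Sampling rate in Hz.
#' @param lag Hemodynamic lag in seconds (default: HRF peak time of `hrf`).
#' @param hrf [hrf_params()] used for the default lag.
#' @param rest_mode `"pooled"` or `"baseline"`.
#' @param var_equal Use Student's pooled-variance t-test instead of Welch.
#' @return Object of class `fus_roi_result`: `time_course`, `z_course`,
#'   `mean_diff_percent`, `t_statistic`, `p_value`, `df`, per-stimulus
#'   means, sample counts, and significance flags at the 0.001 and 1e-5
#'   thresholds.
#' @export
stim_response_stats <- function(tc, protocol, block_rate, lag = NULL,
                                hrf = hrf_params(),
                                rest_mode = c("pooled", "baseline"),
                                var_equal = FALSE) {
  rest_mode <- match.arg(rest_mode)
  if (is.null(lag)) lag <- hrf_peak_time(hrf)
  w <- protocol_windows(length(tc), protocol, block_rate, lag, rest_mode)
  if (length(w$stim) < 2L || length(w$rest) < 2L)
    stopf("need >= 2 samples in both the stimulation and rest windows")
  stim_vals <- tc[w$stim]
  rest_vals <- tc[w$rest]
  tt <- tryCatch(stats::t.test(stim_vals, rest_vals, var.equal = var_equal),
                 error = function(e) NULL)  # zero-variance (noise-free) data
  if (is.null(tt))
    tt <- list(statistic = c(t = if (mean(stim_vals) == mean(rest_vals)) 0 else Inf *
                               sign(mean(stim_vals) - mean(rest_vals))),
               p.value = if (mean(stim_vals) == mean(rest_vals)) 1 else 0,
               parameter = c(df = NA_real_))
  per_stim <- vapply(seq_along(protocol$onsets), function(i) {
    on <- protocol$onsets[i]; du <- protocol$durations[i]
    mean(tc[w$times >= on + lag & w$times < on + du + lag])
  }, numeric(1))
  base_idx <- which(w$times < protocol$baseline_duration)
  z <- if (length(base_idx) >= 2L && stats::sd(tc[base_idx]) > 0)
    zscore_timecourse(tc, base_idx) else rep(NA_real_, length(tc))
  structure(list(
    time_course = as.numeric(tc),
    z_course = z,
    mean_diff_percent = mean(stim_vals) - mean(rest_vals),
    t_statistic = unname(tt$statistic),
    p_value = tt$p.value,
    df = unname(tt$parameter),
    per_stimulus_means = per_stim,
    n_stim = length(stim_vals),
    n_pre = length(rest_vals),
    lag = lag,
    rest_mode = rest_mode,
    test = if (var_equal) "student" else "welch",
    significant_p001 = tt$p.value < 1e-3,
    significant_p1e5 = tt$p.value < 1e-5
  ), class = "fus_roi_result")
}

#' @export
print.fus_roi_result <- function(x, ...) {
  cat(sprintf(
    "ROI response: mean difference = %.3g%%, t = %.3g (df %.3g), P = %.3g (%s, %s rest)\n",
    x$mean_diff_percent, x$t_statistic, x$df, x$p_value, x$test,
    x$rest_mode))
  invisible(x)
}

# Mean of `img` over every (nr x nc) window via summed-area table; returns
# a matrix indexed by the window's top-left pixel.
window_means <- function(img, nr, nc) {
  nz <- nrow(img); nx <- ncol(img)
  ii <- matrix(0, nz + 1, nx + 1)  # integral image, zero-padded top/left
  ii[-1, -1] <- t(apply(apply(img, 2, cumsum), 1, cumsum))
  r <- seq_len(nz - nr + 1L)
  cc <- seq_len(nx - nc + 1L)
  (ii[r + nr, cc + nc, drop = FALSE] - ii[r, cc + nc, drop = FALSE] -
      ii[r + nr, cc, drop = FALSE] + ii[r, cc, drop = FALSE]) / (nr * nc)
}

#' Select reactive and nonreactive ROIs
#'
#' Scans all candidate windows of the requested physical size over the
#' grid, restricted to well-vascularized locations (window mean of the
#' power Doppler image at or above its `vascular_quantile` quantile,
#' default the 70th percentile). Reactive ROIs maximize the window-mean
#' t-score; nonreactive ROIs minimize the window-mean `|t|`. Selections
#' are non-overlapping and ties break deterministically by (row, column)
#' order. If the t-map is all zero the ranking falls back to vascular
#' intensity with a warning.
#'
#' @param act A `fus_activation_map`.
#' @param pd_mean Mean power Doppler image (vascular anatomy), same grid.
#' @param roi_size_m ROI edge length in meters (default 2 mm).
#' @param n_each Number of ROIs of each class (default 1).
#' @param vascular_quantile Quantile of the window-mean power Doppler
#'   distribution below which candidate windows are discarded (default
#'   0.7: only the 30% most vascular windows compete).
#' @param spacing_z,spacing_x Pixel spacings in meters.
#' @return List with `reactive` and `nonreactive`: lists of [roi_spec()].
#' @export
select_rois <- function(act, pd_mean, roi_size_m = 2e-3, n_each = 1L,
                        vascular_quantile = 0.7,
                        spacing_z = 2e-4, spacing_x = 2e-4) {
  tmap <- act$t_score
  stopifnot(identical(dim(tmap), dim(pd_mean)))
  nr <- max(1L, round(roi_size_m / spacing_z))
  nc <- max(1L, round(roi_size_m / spacing_x))
  if (nr > nrow(pd_mean) || nc > ncol(pd_mean))
    stopf("ROI size exceeds the grid")
  t0 <- tmap
  t0[!is.finite(t0)] <- 0
  wt <- window_means(t0, nr, nc)
  wa <- window_means(abs(t0), nr, nc)
  wv <- window_means(pd_mean, nr, nc)
  # gate candidate windows to the most vascular ones: window-mean PD at or
  # above the vascular_quantile quantile of all window means
  thr <- stats::quantile(wv, vascular_quantile, names = FALSE)
  cand <- which(wv >= thr, arr.ind = TRUE)
  if (!nrow(cand)) stopf("no candidate windows above the vascular threshold")
  degenerate <- all(t0 == 0)
  if (degenerate) {
    warnf("t-score map is all zero; falling back to vascular-intensity ordering")
  }
  key_react <- if (degenerate) wv[cand] else wt[cand]
  key_nonre <- if (degenerate) wv[cand] else wa[cand]
  pick <- function(key, decreasing) {
    ord <- order(key, cand[, 1], cand[, 2],
                 decreasing = c(decreasing, FALSE, FALSE), method = "radix")
    chosen <- matrix(0L, 0L, 2L)
    out <- list()
    for (i in ord) {
      r0 <- cand[i, 1]; c0 <- cand[i, 2]
      if (nrow(chosen)) {
        ov <- abs(chosen[, 1] - r0) < nr & abs(chosen[, 2] - c0) < nc
        if (any(ov)) next
      }
      chosen <- rbind(chosen, c(r0, c0))
      out[[length(out) + 1L]] <- c(r0, c0)
      if (length(out) == n_each) break
    }
    out
  }
  react <- pick(key_react, decreasing = TRUE)
  nonre <- pick(key_nonre, decreasing = FALSE)
  mk <- function(lst, label) lapply(lst, function(rc)
    roi_from_pixels(rc[1], rc[2], nr, nc, spacing_z, spacing_x, label))
  list(reactive = mk(react, "reactive"),
       nonreactive = mk(nonre, "nonreactive"))
}
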
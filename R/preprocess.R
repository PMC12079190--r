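# Conditioning of power Doppler series for statistics: motion correction,
# spatial smoothing, voxel normalization, temporal smoothing. The pipeline
# order is fixed: motion -> spatial smooth -> normalize -> temporal smooth.

series_values <- function(series) {
  if (inherits(series, "fus_pd_series")) series$images
  else if (inherits(series, "fus_norm_series")) series$values
  else stopf("expected a fus_pd_series or fus_norm_series")
}

series_replace <- function(series, values, step = NULL) {
  if (inherits(series, "fus_pd_series")) series$images <- values
  else series$values <- values
  if (!is.null(step))
    attr(series, "steps") <- c(attr(series, "steps"), step)
  series
}

# Subpixel translation estimate img ~ ref shifted by (+dz, +dx), from the
# cross-correlation peak with 3-point parabolic interpolation per axis.
estimate_shift <- function(ref, img) {
  a <- ref - mean(ref)
  b <- img - mean(img)
  if (sum(abs(a)) == 0 || sum(abs(b)) == 0) return(c(NA_real_, NA_real_))
  cc <- Re(stats::fft(stats::fft(b) * Conj(stats::fft(a)), inverse = TRUE))
  nz <- nrow(cc); nx <- ncol(cc)
  pk <- arrayInd(which.max(cc), dim(cc))
  wrap <- function(i, n) ifelse(i - 1L > n / 2, i - 1L - n, i - 1L)
  para <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (den >= 0) 0 else max(min(0.5 * (cm - cp) / den, 0.5), -0.5)
  }
  iz <- pk[1]; ix <- pk[2]
  zm <- cc[if (iz == 1) nz else iz - 1L, ix]
  zp <- cc[if (iz == nz) 1L else iz + 1L, ix]
  xm <- cc[iz, if (ix == 1) nx else ix - 1L]
  xp <- cc[iz, if (ix == nx) 1L else ix + 1L]
  c(wrap(iz, nz) + para(zm, cc[iz, ix], zp),
    wrap(ix, nx) + para(xm, cc[iz, ix], xp))
}

#' Motion-correct a power Doppler series
#'
#' Registers every frame to a reference frame by subpixel translation: the
#' displacement is estimated from the cross-correlation peak (parabolic
#' subpixel interpolation) and undone by bilinear resampling. This is a
#' deliberate, documented simplification of fully nonrigid scalp-motion
#' correction; externally computed per-frame displacements can be supplied
#' instead via `displacements`.
#'
#' @param pd A `fus_pd_series` (>= 2 frames).
#' @param reference_index Frame used as the registration target (default 1).
#' @param displacements Optional data frame with columns `dz`, `dx` (pixels,
#'   one row per frame) to apply directly, bypassing estimation.
#' @return The corrected `fus_pd_series`; `$motion_log` is a data frame
#'   `(frame, dz, dx)` of the displacements that were removed. Frames with
#'   no registration signal (all-constant) are left untouched with a
#'   warning and `NA` in the log.
#' @export
correct_motion <- function(pd, reference_index = 1L, displacements = NULL) {
  stopifnot(inherits(pd, "fus_pd_series"))
  d <- dim(pd$images)
  if (d[1] < 2L) stopf("motion correction needs at least 2 frames")
  ref <- pd$images[reference_index, , ]
  log <- data.frame(frame = seq_len(d[1]), dz = 0, dx = 0)
  flat <- FALSE
  for (t in seq_len(d[1])) {
    if (t == reference_index && is.null(displacements)) next
    if (is.null(displacements)) {
      sh <- estimate_shift(ref, pd$images[t, , ])
    } else {
      sh <- c(displacements$dz[t], displacements$dx[t])
    }
    if (any(is.na(sh))) {
      flat <- TRUE
      log$dz[t] <- NA_real_; log$dx[t] <- NA_real_
      next
    }
    log$dz[t] <- sh[1]; log$dx[t] <- sh[2]
    if (sh[1] != 0 || sh[2] != 0)
      pd$images[t, , ] <- shift_image(pd$images[t, , ], -sh[1], -sh[2])
  }
  if (flat)
    warnf("some frames had no registration signal; identity transform kept")
  pd$motion_log <- log
  attr(pd, "steps") <- c(attr(pd, "steps"),
                         sprintf("motion(ref=%d)", reference_index))
  pd
}

#' Spatial Gaussian smoothing
#'
#' Per-frame 2-D Gaussian convolution with standard deviation `sigma`
#' pixels and reflective (symmetric) boundary handling; `sigma = 0` is the
#' identity.
#'
#' @param series `fus_pd_series` or `fus_norm_series`.
#' @param sigma Gaussian standard deviation in pixels (default 1).
#' @return Series of the same class with smoothed frames.
#' @export
spatial_smooth <- function(series, sigma = 1) {
  if (sigma < 0) stopf("sigma must be >= 0")
  if (sigma == 0) return(series)
  vals <- series_values(series)
  d <- dim(vals)
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  cz <- conv_matrix_reflect(d[2], k)
  cx <- conv_matrix_reflect(d[3], k)
  for (t in seq_len(d[1])) vals[t, , ] <- cz %*% vals[t, , ] %*% t(cx)
  series_replace(series, vals, sprintf("spatial_smooth(sigma=%g)", sigma))
}

#' Voxelwise normalization
#'
#' Removes each voxel's mean over a reference window. In `"percent_change"`
#' mode (the default, matching percent rCBF/CBV reporting) the result is
#' `100 * (x - mu_ref) / mu_ref`; voxels whose reference mean is not
#' strictly positive are flagged invalid (all-`NaN`) and excluded
#' downstream. In `"demean"` mode the result is `x - mu_ref` (idempotent).
#'
#' @param series `fus_pd_series` (or `fus_norm_series` for re-demeaning).
#' @param mode `"percent_change"` or `"demean"`.
#' @param reference_window Length-2 numeric `c(t0, t1)` in seconds
#'   (half-open, against block timestamps), or an integer vector of block
#'   indices. Defaults to the pre-stimulus baseline of `protocol`, or the
#'   whole series when neither is given.
#' @param protocol Optional [stimulus_protocol()] supplying the baseline
#'   window.
#' @return Object of class `fus_norm_series` with `$values`
#'   `(block_time, z, x)`, `$invalid` (logical map), and the normalization
#'   provenance.
#' @export
normalize_voxels <- function(series, mode = c("percent_change", "demean"),
                             reference_window = NULL, protocol = NULL) {
  mode <- match.arg(mode)
  vals <- series_values(series)
  d <- dim(vals)
  ts <- series$block_timestamps
  if (is.null(reference_window)) {
    if (!is.null(protocol)) reference_window <- c(0, protocol$baseline_duration)
    else reference_window <- c(0, Inf)
  }
  if (length(reference_window) == 2L && !is.integer(reference_window)) {
    ref_idx <- which(ts >= reference_window[1] & ts < reference_window[2])
  } else {
    ref_idx <- as.integer(reference_window)
  }
  if (!length(ref_idx)) stopf("reference window contains no blocks")
  dim(vals) <- c(d[1], d[2] * d[3])
  mu <- colMeans(vals[ref_idx, , drop = FALSE])
  invalid <- rep(FALSE, length(mu))
  if (mode == "percent_change") {
    invalid <- !(mu > 0) | !is.finite(mu)
    out <- 100 * sweep(vals, 2L, mu, "-")
    out <- sweep(out, 2L, ifelse(invalid, NA_real_, mu), "/")
  } else {
    invalid <- !is.finite(mu)
    out <- sweep(vals, 2L, mu, "-")
  }
  out[, invalid] <- NaN
  dim(out) <- d
  prior_invalid <- if (inherits(series, "fus_norm_series")) series$invalid
                   else matrix(FALSE, d[2], d[3])
  structure(list(
    values = out,
    block_rate = series$block_rate,
    block_timestamps = ts,
    pixel_spacing_z = series$pixel_spacing_z,
    pixel_spacing_x = series$pixel_spacing_x,
    normalization_mode = mode,
    reference_blocks = ref_idx,
    invalid = matrix(invalid, d[2], d[3]) | prior_invalid,
    motion_log = series$motion_log
  ), class = "fus_norm_series",
  steps = c(attr(series, "steps"), sprintf("normalize(%s)", mode)))
}

#' @export
print.fus_norm_series <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "Normalized series (%s): %d frames of %d x %d at %g Hz, %d invalid voxel(s)\n",
    x$normalization_mode, d[1], d[2], d[3], x$block_rate, sum(x$invalid)))
  invisible(x)
}

#' Temporal moving-average smoothing
#'
#' Centered moving average over `window` time points per voxel (default 5).
#' Edges use shrinking (truncated) windows; `window = 1` is the identity.
#'
#' @param series `fus_pd_series` or `fus_norm_series`.
#' @param window Odd positive integer window length.
#' @return Series of the same class.
#' @export
temporal_smooth <- function(series, window = 5L) {
  if (!is_count(window) || window < 1L || window %% 2L == 0L)
    stopf("window must be an odd positive integer")
  vals <- series_values(series)
  d <- dim(vals)
  dim(vals) <- c(d[1], d[2] * d[3])
  vals <- moving_average_cols(vals, as.integer(window))
  dim(vals) <- d
  series_replace(series, vals, sprintf("temporal_smooth(window=%d)", window))
}

#' Full preprocessing chain
#'
#' Applies, in this fixed order: motion correction, spatial Gaussian
#' smoothing (sigma = 1), voxelwise normalization against the pre-stimulus
#' baseline, and a 5-point temporal moving average. Each step can be
#' disabled; the executed order is recorded in the `"steps"` attribute.
#'
#' @param pd A `fus_pd_series`.
#' @param protocol [stimulus_protocol()] supplying the baseline window.
#' @param motion_correct Logical (default TRUE).
#' @param reference_index Registration reference frame.
#' @param sigma Spatial smoothing sigma in pixels (0 disables).
#' @param mode Normalization mode, see [normalize_voxels()].
#' @param reference_window Optional explicit reference window.
#' @param window Temporal smoothing window (1 disables).
#' @return A `fus_norm_series`.
#' @export
preprocess_series <- function(pd, protocol, motion_correct = TRUE,
                              reference_index = 1L, sigma = 1,
                              mode = "percent_change",
                              reference_window = NULL, window = 5L) {
  stopifnot(inherits(pd, "fus_pd_series"))
  if (motion_correct) pd <- correct_motion(pd, reference_index)
  pd <- spatial_smooth(pd, sigma)
  ns <- normalize_voxels(pd, mode = mode,
                         reference_window = reference_window,
                         protocol = protocol)
  temporal_smooth(ns, window)
}
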
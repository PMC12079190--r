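# Voxelwise GLM activation mapping: gamma HRF, design matrix, OLS fit,
# Benjamini-Hochberg FDR thresholding.

#' Gamma hemodynamic response function kernel
#'
#' Samples the delayed gamma HRF
#' `h(t) = ((t - delta) / tau)^(n - 1) * exp(-(t - delta) / tau)` for
#' `t >= delta` (0 before `delta`), peak-normalized so `max(h) = 1`. With
#' the default parameters (tau = 0.7 s, delta = 1.5 s, n = 3) the analytic
#' peak is at `delta + (n - 1) * tau = 2.9` s.
#'
#' @param params [hrf_params()].
#' @param dt Sampling interval in seconds.
#' @param duration Kernel support in seconds (default 15, ample for the
#'   default parameters).
#' @return Numeric kernel sampled at `t = 0, dt, 2 dt, ...`; attribute
#'   `"dt"` records the sampling interval.
#' @export
gamma_hrf <- function(params = hrf_params(), dt, duration = 15) {
  stopifnot(inherits(params, "fus_hrf_params"))
  if (dt <= 0) stopf("dt must be positive")
  if (duration <= params$delta)
    stopf("duration must exceed the onset delay delta")
  t <- seq(0, duration, by = dt)
  s <- pmax(t - params$delta, 0) / params$tau
  h <- ifelse(t >= params$delta, s^(params$n - 1) * exp(-s), 0)
  m <- max(h)
  if (m <= 0) stopf("degenerate HRF: kernel is identically zero")
  structure(h / m, dt = dt)
}

#' Build the GLM design matrix
#'
#' The task regressor is the stimulus boxcar convolved with the HRF kernel,
#' sampled at the block timestamps (block centers) and peak-normalized to 1
#' so the fitted slope is directly interpretable as the peak response in
#' the data's units (percent change under the default normalization). The
#' second column is the intercept; an optional linear drift column can be
#' added.
#'
#' @param protocol [stimulus_protocol()] with at least one stimulus.
#' @param kernel HRF kernel from [gamma_hrf()], sampled at `1 / block_rate`.
#' @param n_frames Number of time points (may truncate or extend past the
#'   protocol; the regressor is zero where no stimulus response reaches).
#' @param block_rate Sampling rate in Hz.
#' @param add_drift Add a linear drift column (default FALSE).
#' @return Object of class `fus_design_matrix`: a numeric matrix
#'   `(n_frames x k)` with columns `task`, `intercept` (and `drift`),
#'   attributes `block_rate` and `times`.
#' @export
build_design_matrix <- function(protocol, kernel, n_frames, block_rate,
                                add_drift = FALSE) {
  if (length(protocol$onsets) == 0L)
    stopf("the design needs at least one stimulus (task column would be zero)")
  kdt <- attr(kernel, "dt")
  if (!is.null(kdt) && abs(kdt - 1 / block_rate) > 1e-9)
    stopf("kernel sampled at dt = %g s but block rate implies %g s",
          kdt, 1 / block_rate)
  times <- (seq_len(n_frames) - 0.5) / block_rate
  box <- rep(0, n_frames)
  for (i in seq_along(protocol$onsets)) {
    on <- protocol$onsets[i]
    box[times >= on & times < on + protocol$durations[i]] <- 1
  }
  task <- stats::convolve(box, rev(as.numeric(kernel)),
                          type = "open")[seq_len(n_frames)]
  m <- max(abs(task))
  if (m <= 0)
    stopf("task regressor is identically zero over the sampled frames")
  task <- task / m
  x <- cbind(task = task, intercept = 1)
  if (add_drift) x <- cbind(x, drift = scale(times, scale = FALSE)[, 1])
  if (qr(x)$rank < ncol(x)) stopf("design matrix is rank deficient")
  structure(x, block_rate = block_rate, times = times,
            class = c("fus_design_matrix", class(x)))
}

#' Fit the voxelwise GLM
#'
#' Ordinary least squares of every voxel's time course on the design
#' matrix. The test statistic is `t = beta_task / se(beta_task)` with
#' `n_time - k` degrees of freedom; p-values are two-sided by default
#' (one-sided `"greater"` restricts to signal increases). Voxels flagged
#' invalid by preprocessing, or containing non-finite values, get `NaN`
#' maps.
#'
#' When the series went through the temporal moving average, pass its
#' window as `temporal_smoothing`: the regressors are then smoothed with
#' the same filter (the model is `y = S X b + S e`), the standard error of
#' the slope uses the induced noise covariance `V = S S'`, and the
#' Satterthwaite effective degrees of freedom replace `n - k`. Without
#' this correction the serial correlation introduced by smoothing inflates
#' the t-scores of pure-noise voxels.
#'
#' @param series A `fus_norm_series` (or any series object), or a plain
#'   numeric matrix `(n_time x n_voxels)`.
#' @param design [build_design_matrix()] output.
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @param temporal_smoothing Odd window length of the moving average the
#'   data were smoothed with (`NULL` or 1: no correction).
#' @return Object of class `fus_activation_map` with matrices `beta`
#'   (task slope), `t_score`, `p_value` (and, after [fdr_correct()] or via
#'   [activation_pipeline()], `q_value`/`mask`), plus `dof` and metadata.
#'   For matrix input the maps are returned as vectors.
#' @export
fit_glm <- function(series, design, alternative = c("two.sided", "greater"),
                    temporal_smoothing = NULL) {
  alternative <- match.arg(alternative)
  as_matrix_input <- is.matrix(series) && !inherits(series, "fus_design_matrix")
  if (as_matrix_input) {
    y <- series
    grid <- NULL
  } else {
    vals <- series_values(series)
    d <- dim(vals)
    grid <- d[2:3]
    y <- vals
    dim(y) <- c(d[1], d[2] * d[3])
  }
  x <- unclass(design)
  n <- nrow(x); k <- ncol(x)
  if (nrow(y) != n) stopf("series has %d frames but design has %d rows",
                          nrow(y), n)
  if (n <= k) stopf("need more time points (%d) than regressors (%d)", n, k)
  if (qr(x)$rank < k) stopf("design matrix is rank deficient")
  valid <- colSums(!is.finite(y)) == 0L
  smooth_w <- temporal_smoothing %||% 1L
  if (smooth_w > 1L) {
    s <- smoothing_matrix(n, as.integer(smooth_w))
    x <- s %*% x
    v <- tcrossprod(s)
  } else {
    v <- NULL
  }
  xtx_inv <- chol2inv(chol(crossprod(x)))
  if (is.null(v)) {
    dof <- n - k
    var_scale <- xtx_inv[1, 1]   # Var(beta1) = sigma2 * var_scale
    rss_scale <- dof             # E[RSS] = sigma2 * rss_scale
  } else {
    a <- xtx_inv %*% t(x)        # (X'X)^-1 X'
    ava <- a %*% v %*% t(a)
    var_scale <- ava[1, 1]
    rv <- v - x %*% (a %*% v)    # R V with R = I - X(X'X)^-1 X'
    rss_scale <- sum(diag(rv))
    dof <- rss_scale^2 / sum(rv * t(rv))  # tr(RV)^2 / tr(RVRV)
  }
  beta <- t_sc <- p <- rep(NaN, ncol(y))
  if (any(valid)) {
    yv <- y[, valid, drop = FALSE]
    b <- xtx_inv %*% crossprod(x, yv)
    res <- yv - x %*% b
    sigma2 <- colSums(res^2) / rss_scale
    se1 <- sqrt(pmax(sigma2 * var_scale, 0))
    tv <- ifelse(se1 > 0, b[1, ] / se1, ifelse(b[1, ] == 0, 0, Inf * sign(b[1, ])))
    pv <- if (alternative == "two.sided") 2 * stats::pt(-abs(tv), dof)
          else stats::pt(tv, dof, lower.tail = FALSE)
    beta[valid] <- b[1, ]; t_sc[valid] <- tv; p[valid] <- pmin(pv, 1)
    intercept <- rep(NaN, ncol(y)); intercept[valid] <- b[2, ]
  } else {
    intercept <- rep(NaN, ncol(y))
  }
  shape <- function(v) if (is.null(grid)) v else matrix(v, grid[1], grid[2])
  structure(list(
    beta = shape(beta),
    intercept = shape(intercept),
    t_score = shape(t_sc),
    p_value = shape(p),
    q_value = NULL,
    mask = NULL,
    dof = dof,
    alternative = alternative,
    design_columns = colnames(x)
  ), class = "fus_activation_map")
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjustment of a p-value map over its valid (non-`NaN`) entries;
#' the activation mask keeps voxels with adjusted `q_value < q`. `NaN`
#' p-values propagate.
#'
#' @param p Numeric vector or matrix of p-values in `[0, 1]` (or `NaN`).
#' @param q FDR threshold (default `1e-3`, matching a corrected
#'   `P < 0.001` map).
#' @return List with `q_value` (same shape as `p`), `mask` (logical) and
#'   `q`.
#' @export
fdr_correct <- function(p, q = 1e-3) {
  pv <- as.vector(p)
  valid <- is.finite(pv)
  if (any(pv[valid] < 0 | pv[valid] > 1))
    stopf("p-values must lie in [0, 1]")
  qv <- rep(NaN, length(pv))
  qv[valid] <- stats::p.adjust(pv[valid], method = "BH")
  mask <- !is.na(qv) & is.finite(qv) & qv < q
  if (!is.null(dim(p))) {
    dim(qv) <- dim(p); dim(mask) <- dim(p)
  }
  list(q_value = qv, mask = mask, q = q)
}

#' @export
print.fus_activation_map <- function(x, ...) {
  nv <- sum(is.finite(as.vector(x$p_value)))
  cat(sprintf("Activation map: %d valid voxel(s), dof = %d (%s test)\n",
              nv, x$dof, x$alternative))
  if (!is.null(x$mask))
    cat(sprintf("  %d voxel(s) pass FDR q < %g\n", sum(x$mask),
                x$threshold$q))
  invisible(x)
}

#' Power Doppler to FDR-thresholded activation map
#'
#' End-to-end statistical mapping: preprocessing
#' ([preprocess_series()]), HRF-convolved design matrix, voxelwise GLM and
#' Benjamini-Hochberg FDR thresholding at `q` (default `1e-3`). The result
#' records both the FDR-corrected mask and the count of voxels passing the
#' same threshold uncorrected.
#'
#' @param pd A `fus_pd_series`.
#' @param protocol [stimulus_protocol()].
#' @param hrf [hrf_params()].
#' @param q FDR threshold (default `1e-3`).
#' @param alternative Sidedness of the voxel test.
#' @param window Temporal smoothing window, forwarded both to
#'   [preprocess_series()] and to the GLM's serial-correlation correction.
#' @param ... Further preprocessing options passed to
#'   [preprocess_series()].
#' @return A `fus_activation_map` with `q_value`, `mask`, and `threshold`
#'   metadata; the attribute `"series"` carries the preprocessed series for
#'   downstream ROI analysis.
#' @export
activation_pipeline <- function(pd, protocol, hrf = hrf_params(), q = 1e-3,
                                alternative = "two.sided", window = 5L,
                                ...) {
  ns <- preprocess_series(pd, protocol, window = window, ...)
  kern <- gamma_hrf(hrf, dt = 1 / ns$block_rate)
  des <- build_design_matrix(protocol, kern, dim(ns$values)[1],
                             ns$block_rate)
  act <- fit_glm(ns, des, alternative = alternative,
                 temporal_smoothing = window)
  fd <- fdr_correct(act$p_value, q)
  act$q_value <- fd$q_value
  act$mask <- fd$mask
  act$threshold <- list(q = q, correction = "BH",
                        p_threshold_uncorrected = q,
                        n_uncorrected = sum(act$p_value < q, na.rm = TRUE),
                        n_corrected = sum(fd$mask))
  act$hrf <- unclass(hrf)
  attr(act, "series") <- ns
  attr(act, "steps") <- attr(ns, "steps")
  act
}
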
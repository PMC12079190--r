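# Image quality metrics: contrast-to-noise ratio and full width at half
# maximum of intensity profiles.

#' Contrast-to-noise ratio
#'
#' CNR between a signal region and a background region of a (linear-power)
#' power Doppler image. The default `"amplitude"` convention is
#' `20 * log10((mu_s - mu_b) / sd_b)`; the alternative `"power"` convention
#' uses `10 * log10`. The convention is always recorded alongside the value
#' so the number is only ever compared under its own definition. A
#' non-positive contrast (`mu_s <= mu_b`) is reported as `-Inf`.
#'
#' @param image Numeric image (linear power Doppler values).
#' @param signal_mask,background_mask Disjoint nonempty logical masks.
#' @param convention `"amplitude"` (20 log10, default) or `"power"`
#'   (10 log10).
#' @return List with `cnr_db`, `convention`, `mu_signal`, `mu_background`,
#'   `sd_background`, and the mask sizes.
#' @export
cnr <- function(image, signal_mask, background_mask,
                convention = c("amplitude", "power")) {
  convention <- match.arg(convention)
  stopifnot(identical(dim(image), dim(signal_mask)),
            identical(dim(image), dim(background_mask)))
  if (!any(signal_mask) || !any(background_mask))
    stopf("signal and background masks must be nonempty")
  if (any(signal_mask & background_mask))
    stopf("signal and background masks must be disjoint")
  mu_s <- mean(image[signal_mask])
  mu_b <- mean(image[background_mask])
  sd_b <- stats::sd(image[background_mask])
  if (!is.finite(sd_b) || sd_b <= 0)
    stopf("background has zero variance; CNR undefined")
  ratio <- (mu_s - mu_b) / sd_b
  fac <- if (convention == "amplitude") 20 else 10
  cnr_db <- if (ratio > 0) fac * log10(ratio) else -Inf
  list(cnr_db = cnr_db, convention = convention,
       mu_signal = mu_s, mu_background = mu_b, sd_background = sd_b,
       n_signal = sum(signal_mask), n_background = sum(background_mask))
}

#' Full width at half maximum of an intensity profile
#'
#' Measures the FWHM of a 1-D profile (a resolution proxy for vessel or
#' point-target cross-sections). The profile's background, estimated as the
#' median of its edge samples, is subtracted first; the half-maximum
#' crossings on either side of the (unique) peak are located by linear
#' interpolation and the width is converted to micrometers through the
#' pixel spacing. Profiles narrower than one sample are flagged as
#' sub-sample (`at_resolution_floor`).
#'
#' @param x Numeric profile, or an image matrix together with `line` to
#'   extract one.
#' @param pixel_spacing Sample spacing in meters.
#' @param line For image input: `list(axis = "z" | "x", index = i)`
#'   extracts column (`axis = "z"`, profile along depth) or row
#'   (`axis = "x"`, profile along lateral position) `i`.
#' @param edge_fraction Fraction of samples at each end used for the
#'   background median (default 0.1, at least 1 sample).
#' @return List with `fwhm_um`, `fwhm_px`, `peak_index`, `background`,
#'   `at_resolution_floor`.
#' @export
fwhm_profile <- function(x, pixel_spacing, line = NULL,
                         edge_fraction = 0.1) {
  if (is.matrix(x)) {
    if (is.null(line)) stopf("supply line = list(axis, index) for image input")
    x <- if (line$axis == "z") x[, line$index] else x[line$index, ]
  }
  n <- length(x)
  if (n < 3L) stopf("profile too short")
  ne <- max(1L, floor(edge_fraction * n))
  bg <- stats::median(c(x[seq_len(ne)], x[n - seq_len(ne) + 1L]))
  p <- x - bg
  ipk <- which.max(p)
  pk <- p[ipk]
  if (pk <= 0) stopf("profile has no peak above the background")
  if (sum(p == pk) > 1L) stopf("profile peak is not unique")
  half <- pk / 2
  cross <- function(side) {
    idx <- if (side < 0) rev(seq_len(ipk - 1L)) else (ipk + 1L):n
    if (ipk + side < 1L || ipk + side > n) return(NA_real_)
    prev <- ipk
    for (i in idx) {
      if (p[i] < half) {
        # linear interpolation between samples prev (>= half) and i (< half)
        return(prev + side * (p[prev] - half) / (p[prev] - p[i]))
      }
      prev <- i
    }
    NA_real_
  }
  left <- cross(-1L)
  right <- cross(1L)
  if (is.na(left) || is.na(right))
    stopf("no half-maximum crossing on %s side of the peak",
          if (is.na(left)) "the left" else "the right")
  w_px <- right - left
  list(fwhm_um = w_px * pixel_spacing * 1e6,
       fwhm_px = w_px,
       peak_index = ipk,
       background = bg,
       at_resolution_floor = w_px <= 1)
}

#' Quality report for a power Doppler series
#'
#' Convenience wrapper computing the CNR of the temporal-mean power Doppler
#' image between vessel and background masks.
#'
#' @param pd A `fus_pd_series`.
#' @param signal_mask,background_mask Logical masks (e.g. from
#'   [scene_vessel_mask()] / [scene_background_mask()]).
#' @param convention CNR convention, see [cnr()].
#' @return List with the [cnr()] fields plus the mean image used.
#' @export
quality_report <- function(pd, signal_mask, background_mask,
                           convention = "amplitude") {
  img <- apply(pd$images, c(2, 3), mean)
  rep <- cnr(img, signal_mask, background_mask, convention)
  rep$mean_image <- img
  rep
}
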
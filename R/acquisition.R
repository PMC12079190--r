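#' Ultrafast acquisition parameters
#'
#' Describes the plane-wave compounding scheme that produced a beamformed
#' frame stream: a set of transmit angles is fired repeatedly, the per-angle
#' frames are coherently compounded, and consecutive compounded frames are
#' temporally averaged. The effective pulse repetition frequency is derived
#' as `compound_frame_rate * length(angles_deg) * temporal_averaging_factor`
#' (7 angles x triple averaging x 500 Hz gives 10.5 kHz, i.e. the
#' "approximately 10 kHz" regime of clinical fUS).
#'
#' @param center_frequency Transmit center frequency in Hz (default 7.8 MHz,
#'   the linear-array frequency suited to cortical depths of 1.5-4 cm).
#' @param compound_frame_rate Compounded B-mode frame rate in Hz (default 500).
#' @param angles_deg Ordered transmit steering angles in degrees
#'   (default -6, -4, -2, 0, 2, 4, 6).
#' @param temporal_averaging_factor Number of consecutive compounded frames
#'   averaged to raise SNR (default 3, "triple temporal averaging").
#' @param frames_per_block Compounded frames per power Doppler block
#'   (default 250; 250 frames at 500 Hz yields a 2 Hz Doppler series).
#' @param speed_of_sound Speed of sound in m/s (default 1540).
#' @param pixel_spacing_z,pixel_spacing_x Pixel spacings in meters/pixel
#'   (default 200 um, matching a ~300 um resolution probe).
#' @return An object of class `fus_acq_params`; `$prf` holds the derived
#'   pulse repetition frequency in Hz.
#' @examples
#' acq <- acq_params()
#' acq$prf  # 500 * 7 * 3 = 10500 Hz
#' @export
acq_params <- function(center_frequency = 7.8e6,
                       compound_frame_rate = 500,
                       angles_deg = c(-6, -4, -2, 0, 2, 4, 6),
                       temporal_averaging_factor = 3L,
                       frames_per_block = 250L,
                       speed_of_sound = 1540,
                       pixel_spacing_z = 2e-4,
                       pixel_spacing_x = 2e-4) {
  if (!is.numeric(center_frequency) || center_frequency <= 0)
    stopf("center_frequency must be positive")
  if (!is.numeric(compound_frame_rate) || compound_frame_rate <= 0)
    stopf("compound_frame_rate must be positive")
  if (length(angles_deg) < 1L)
    stopf("at least one transmit angle is required")
  if (!is_count(temporal_averaging_factor) || temporal_averaging_factor < 1)
    stopf("temporal_averaging_factor must be a positive integer")
  if (!is_count(frames_per_block) || frames_per_block < 2)
    stopf("frames_per_block must be an integer >= 2")
  if (speed_of_sound <= 0 || pixel_spacing_z <= 0 || pixel_spacing_x <= 0)
    stopf("speed_of_sound and pixel spacings must be positive")
  acq <- list(
    center_frequency = center_frequency,
    compound_frame_rate = compound_frame_rate,
    angles_deg = as.numeric(angles_deg),
    temporal_averaging_factor = as.integer(temporal_averaging_factor),
    frames_per_block = as.integer(frames_per_block),
    speed_of_sound = speed_of_sound,
    pixel_spacing_z = pixel_spacing_z,
    pixel_spacing_x = pixel_spacing_x
  )
  acq$prf <- compound_frame_rate * length(angles_deg) *
    as.integer(temporal_averaging_factor)
  structure(acq, class = "fus_acq_params")
}

#' @export
print.fus_acq_params <- function(x, ...) {
  cat(sprintf(
    "fUS acquisition: f_c = %.3g MHz, %d angles, %dx temporal averaging\n",
    x$center_frequency / 1e6, length(x$angles_deg),
    x$temporal_averaging_factor))
  cat(sprintf(
    "  compound rate %g Hz, PRF %g Hz, %d frames/block (Doppler rate %g Hz)\n",
    x$compound_frame_rate, x$prf, x$frames_per_block,
    x$compound_frame_rate / x$frames_per_block))
  invisible(x)
}

# Largest non-aliasing axial velocity (m/s) for the slow-time Doppler clock,
# which runs at the compounded frame rate: |f_d| = 2 v f_c / c < rate / 2.
aliasing_velocity_bound <- function(acq) {
  acq$compound_frame_rate * acq$speed_of_sound / (4 * acq$center_frequency)
}

#' Stimulation protocol
#'
#' Block-design stimulation timing: a pre-stimulus baseline followed by
#' stimulus blocks at given onsets/durations.
#'
#' @param baseline_duration Pre-stimulus baseline rest period in seconds.
#' @param onsets Stimulus onset times in seconds (strictly increasing, all
#'   at or after the baseline).
#' @param durations Stimulus durations in seconds (same length as `onsets`).
#' @param total_duration Total recording duration in seconds.
#' @return Object of class `fus_protocol`.
#' @seealso [default_protocol()]
#' @export
stimulus_protocol <- function(baseline_duration, onsets, durations,
                              total_duration) {
  if (length(onsets) != length(durations))
    stopf("onsets and durations must have equal length")
  if (baseline_duration < 0 || total_duration <= 0)
    stopf("durations must be nonnegative and total_duration positive")
  if (length(onsets)) {
    if (any(diff(onsets) <= 0)) stopf("onsets must be strictly increasing")
    if (any(onsets < baseline_duration))
      stopf("every onset must be at or after the baseline period")
    if (any(onsets + durations > total_duration))
      stopf("stimuli must end before total_duration")
    if (any(durations <= 0)) stopf("durations must be positive")
  }
  structure(list(
    baseline_duration = baseline_duration,
    onsets = as.numeric(onsets),
    durations = as.numeric(durations),
    total_duration = total_duration
  ), class = "fus_protocol")
}

#' Default auditory block-design protocol
#'
#' Three 5-s stimulation blocks interspersed with 20-s rest intervals,
#' preceded by a 20-s baseline rest period: onsets at 20, 45 and 70 s with a
#' total duration of 95 s (190 power Doppler frames at 2 Hz).
#'
#' @return A [stimulus_protocol()] object.
#' @examples
#' p <- default_protocol()
#' p$onsets     # 20 45 70
#' p$durations  # 5 5 5
#' @export
default_protocol <- function() {
  stimulus_protocol(baseline_duration = 20,
                    onsets = c(20, 45, 70),
                    durations = c(5, 5, 5),
                    total_duration = 95)
}

#' @export
print.fus_protocol <- function(x, ...) {
  cat(sprintf("Stimulation protocol: %g s baseline, %d stimuli, total %g s\n",
              x$baseline_duration, length(x$onsets), x$total_duration))
  if (length(x$onsets))
    cat("  onsets (s):", paste(x$onsets, collapse = ", "),
        "| durations (s):", paste(x$durations, collapse = ", "), "\n")
  invisible(x)
}

#' Gamma hemodynamic response function parameters
#'
#' Parameters of the delayed gamma HRF `h(t) = ((t-delta)/tau)^(n-1)
#' exp(-(t-delta)/tau)` for `t >= delta` (0 before), peak-normalized to 1.
#' The peak occurs at `delta + (n-1) tau` (2.9 s at the defaults).
#'
#' @param tau Time constant in seconds (default 0.7).
#' @param delta Onset delay in seconds (default 1.5).
#' @param n Dimensionless shape parameter (default 3).
#' @return Object of class `fus_hrf_params`.
#' @export
hrf_params <- function(tau = 0.7, delta = 1.5, n = 3) {
  if (tau <= 0) stopf("tau must be positive")
  if (delta < 0) stopf("delta must be nonnegative")
  if (n < 1) stopf("n must be >= 1")
  structure(list(tau = tau, delta = delta, n = n), class = "fus_hrf_params")
}

# Time of the HRF maximum, used as the default hemodynamic lag.
hrf_peak_time <- function(hrf) hrf$delta + (hrf$n - 1) * hrf$tau

#' Frame-to-frame motion model for the phantom generator
#'
#' Describes tissue motion applied to simulated frames. `"smooth-nonrigid"`
#' (the default) scales a fixed smooth spatial displacement field by a
#' slowly varying temporal path; `"rigid"` translates whole frames along the
#' same temporal path; `"none"` disables motion. The first frame always has
#' zero displacement and the displacement magnitude never exceeds
#' `max_displacement_px`.
#'
#' @param kind One of `"none"`, `"rigid"`, `"smooth-nonrigid"`.
#' @param max_displacement_px Peak displacement in pixels (default 0.5).
#' @param temporal_scale_s Correlation time of the motion path in seconds
#'   (default 10; slow scalp/tissue drift, quasi-static within one
#'   250-frame Doppler block).
#' @param spatial_scale_px Smoothness scale of the nonrigid field in pixels
#'   (default 8).
#' @return Object of class `fus_motion_model`.
#' @export
motion_model <- function(kind = c("smooth-nonrigid", "rigid", "none"),
                         max_displacement_px = 0.5,
                         temporal_scale_s = 10,
                         spatial_scale_px = 8) {
  kind <- match.arg(kind)
  if (max_displacement_px < 0) stopf("max_displacement_px must be >= 0")
  structure(list(kind = kind,
                 max_displacement_px = max_displacement_px,
                 temporal_scale_s = temporal_scale_s,
                 spatial_scale_px = spatial_scale_px),
            class = "fus_motion_model")
}
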